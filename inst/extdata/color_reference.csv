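color,metal,unit,mean,sd,censored_cell
black,Al,ppm,0.51,0.32,FALSE
black,Ba,ppm,1.08,1.67,FALSE
black,Cd,ppb,0.483,0.285,FALSE
black,Cu,ppb,82.8,114.8,FALSE
black,Fe,ppm,2.29,3.98,FALSE
black,Pb,ppb,169.9,106.59,FALSE
blonde,Al,ppm,0.41,0.31,FALSE
blonde,Ba,ppm,NA,NA,TRUE
blonde,Cd,ppb,0.5,0.37,FALSE
blonde,Cu,ppb,69.28,117.61,FALSE
blonde,Fe,ppm,0.44,0.42,FALSE
blonde,Pb,ppb,228.7,100.36,FALSE
light-brown,Al,ppm,0.81,1.19,FALSE
light-brown,Ba,ppm,0.3,0.09,FALSE
light-brown,Cd,ppb,0.45,0.4,FALSE
light-brown,Cu,ppb,70.04,117.72,FALSE
light-brown,Fe,ppm,1.56,2.81,FALSE
light-brown,Pb,ppb,167.8,69.74,FALSE
dark-brown,Al,ppm,0.44,0.31,FALSE
dark-brown,Ba,ppm,1.14,1.9,FALSE
dark-brown,Cd,ppb,0.32,0.17,FALSE
dark-brown,Cu,ppb,14.51,11.93,FALSE
dark-brown,Fe,ppm,0.46,0.26,FALSE
dark-brown,Pb,ppb,174.93,84.09,FALSE
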
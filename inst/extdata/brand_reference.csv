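brand,country,metal,unit,mean,sd,censored_cell
brand1,Italy,Al,ppm,0.42,0.43,FALSE
brand1,Italy,Ba,ppm,NA,NA,TRUE
brand1,Italy,Cd,ppb,0.45,0.39,FALSE
brand1,Italy,Cu,ppb,168.77,174.14,FALSE
brand1,Italy,Fe,ppm,0.41,0.165,FALSE
brand1,Italy,Pb,ppb,240.3,106.4,FALSE
brand2,Iran,Al,ppm,1.59,1.43,FALSE
brand2,Iran,Ba,ppm,1.07,1.34,FALSE
brand2,Iran,Cd,ppb,0.33,0.152,FALSE
brand2,Iran,Cu,ppb,21.4,24.47,FALSE
brand2,Iran,Fe,ppm,5.2,5.71,FALSE
brand2,Iran,Pb,ppb,225.12,106.16,FALSE
brand3,Spain,Al,ppm,0.41,0.26,FALSE
brand3,Spain,Ba,ppm,0.495,0.417,FALSE
brand3,Spain,Cd,ppb,0.85,0.49,FALSE
brand3,Spain,Cu,ppb,41.65,27.53,FALSE
brand3,Spain,Fe,ppm,0.53,0.61,FALSE
brand3,Spain,Pb,ppb,195.17,126.9,FALSE
brand4,Iran,Al,ppm,0.3,0.15,FALSE
brand4,Iran,Ba,ppm,0.26,0.197,FALSE
brand4,Iran,Cd,ppb,0.43,0.23,FALSE
brand4,Iran,Cu,ppb,15.86,10.15,FALSE
brand4,Iran,Fe,ppm,0.5,0.35,FALSE
brand4,Iran,Pb,ppb,155.38,25.42,FALSE
brand5,Spain,Al,ppm,0.46,0.19,FALSE
brand5,Spain,Ba,ppm,0.09,0.028,FALSE
brand5,Spain,Cd,ppb,0.17,0.11,FALSE
brand5,Spain,Cu,ppb,86.2,124.59,FALSE
brand5,Spain,Fe,ppm,0.53,0.35,FALSE
brand5,Spain,Pb,ppb,155.03,53.17,FALSE
brand6,Iran,Al,ppm,0.21,0.12,FALSE
brand6,Iran,Ba,ppm,0.125,0.077,FALSE
brand6,Iran,Cd,ppb,0.75,0.212,FALSE
brand6,Iran,Cu,ppb,151.75,208.8,FALSE
brand6,Iran,Fe,ppm,0.49,0.36,FALSE
brand6,Iran,Pb,ppb,189.95,135.57,FALSE
brand7,Italy,Al,ppm,0.28,0.23,FALSE
brand7,Italy,Ba,ppm,1.69,2.44,FALSE
brand7,Italy,Cd,ppb,0.5,0.14,FALSE
brand7,Italy,Cu,ppb,21.03,10.98,FALSE
brand7,Italy,Fe,ppm,1.52,1.82,FALSE
brand7,Italy,Pb,ppb,118.56,77.79,FALSE
brand8,Germany,Al,ppm,0.68,0.14,FALSE
brand8,Germany,Ba,ppm,0.376,0.261,FALSE
brand8,Germany,Cd,ppb,NA,NA,TRUE
brand8,Germany,Cu,ppb,13.9,13.71,FALSE
brand8,Germany,Fe,ppm,0.32,0.1,FALSE
brand8,Germany,Pb,ppb,203.23,54.19,FALSE
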
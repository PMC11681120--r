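parameter,bidmc,capnobase,perform_af,perform_non_af,wesad,ecg_ppg,ecg_rppg,ppg_rppg
AVNN,***,***,-,***,***,***,***,***
SDNN,***,***,-,***,-,***,-,-
RMSSD,***,***,-,***,-,***,-,-
SEM,***,***,-,***,-,***,-,-
PNN50,***,***,***,***,-,-,-,-
PIP,-,-,***,-,-,-,-,-
IALS,-,-,***,-,-,-,-,-
PSS,-,-,***,-,-,-,-,-
PAS,-,-,***,-,-,-,-,-
HF_NORM,-,-,***,-,-,***,-,-
HF_PEAK,***,***,***,***,-,***,***,***
HF_POWER,***,***,***,***,-,***,-,-
LF_NORM,***,-,***,***,-,***,-,-
LF_PEAK,***,***,***,***,***,***,***,***
LF_POWER,***,***,***,***,-,***,-,-
LF_HF,***,-,***,-,-,-,-,-
VLF_NORM,-,-,***,-,-,-,-,-
VLF_POWER,-,-,***,***,-,***,***,***
TOTAL_POWER,-,***,***,***,-,***,***,***
BETA,***,***,***,-,-,***,-,-
SD1,***,***,-,***,-,***,-,-
SD2,***,***,***,***,-,***,-,-
ALPHA1,-,-,***,***,-,-,-,-
ALPHA2,-,***,***,-,***,***,-,-
MSE1,-,***,***,-,***,***,-,-
MSE2,***,-,***,***,***,***,***,***
MSE3,***,***,***,***,***,***,***,***
MSE4,***,***,***,***,***,***,***,***
MSE5,***,***,**,***,***,***,***,***
MSE6,***,***,***,***,***,***,***,***
MSE7,***,***,***,***,***,***,***,***
MSE8,***,***,***,***,***,***,***,***
MSE9,***,***,***,***,***,***,***,***
MSE10,-,-,***,***,-,***,-,-
MSE11,-,-,***,-,-,***,-,-
MSE12,-,-,***,-,-,***,-,-
MSE13,-,***,***,-,-,***,-,-
MSE14,-,***,***,-,-,***,-,-
MSE15,-,***,***,-,-,***,-,-
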
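curve_type,view,mean_mm,sd_mm,reported_cv_percent
single_thoracic,front,2.13,0.04,2
single_thoracic,clockwise5,2.16,0.02,1
single_thoracic,counterclockwise5,2.19,0.03,1
double,front,2.10,0.09,4
double,clockwise5,2.14,0.07,3
double,counterclockwise5,2.21,0.05,2
thoracolumbar,front,2.89,0.02,1
thoracolumbar,clockwise5,2.95,0.03,1
thoracolumbar,counterclockwise5,2.98,0.04,1
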
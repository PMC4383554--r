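id,procedure,mca_left_mm,mca_right_mm,n_left,n_right,total_volume_ml
1,MVR,2.6,2.7,502,596,0.021
2,CABG+MVR,2.6,2.8,349,322,0.016
3,CABG+MVR,2.9,2.6,2785,3691,0.005
4,CABGx3,2.6,2.9,409,383,0.0003
5,CABG+AVR,3.5,2.6,2080,2144,0.12
6,MVR,3.3,3.2,480,886,0.003
7,CABG,3.0,3.1,674,843,0.04
8,CABGx3,2.6,2.8,196,175,0.0002
9,CABGx3,2.9,2.8,950,601,0.022
10,CABGx2,2.6,2.7,284,317,0.01
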
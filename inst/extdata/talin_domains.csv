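name,l0,L0,A,k_unf0,dx_unf,k_ref0,dx_ref,unfoldable
R1,5,75,0.8,6.808e-04,2.5,341.6,2,TRUE
R2,5,70,0.8,3.708e-04,2.5,555.5,2,TRUE
R3,5,70,0.8,1.548e-02,4.0,22.73,2,TRUE
R4,5,70,0.8,2.019e-04,2.5,903.3,2,TRUE
R5,5,75,0.8,7.739e-03,2.5,48.87,2,TRUE
R6,5,72,0.8,4.215e-03,2.5,79.46,2,TRUE
R7,5,85,0.8,1.100e-04,2.5,1469,2,TRUE
R8,5,70,0.8,3.262e-05,2.5,3883,2,TRUE
R9,5,70,0.8,0,2.5,1000,2,FALSE
R10,5,72,0.8,3.111e-03,2.5,101.3,2,TRUE
R11,5,71,0.8,2.295e-03,2.5,129.2,2,TRUE
R12,5,70,0.8,5.990e-05,2.5,2388,2,TRUE
R13DD,5,60,0.8,0,2.5,1000,2,FALSE
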
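system,A_lift_off,A_collapse,pi_collapse,A_max,pi_max,Cs1_max,chi,a_LE_LC
azolectin,61.6,4.2,45.0,35.8,24.5,68.4,0.068,-1.79
azolectin_P2,61.9,4.2,40.9,20.0,42.1,64.3,0.068,-1.30
azolectin_P4,61.6,4.4,40.2,38.0,27.8,72.5,0.071,-1.53
azolectin_P5,61.8,4.8,42.0,42.5,19.2,64.7,0.078,-1.33
azolectin_P6,61.7,4.2,41.6,38.9,22.6,63.1,0.068,-1.36
lecithin,62.0,4.2,35.8,30.6,19.9,37.7,0.068,-0.673
lecithin_P2,61.8,4.6,38.6,31.0,22.4,42.6,0.074,-0.765
lecithin_P4,62.0,5.0,39.8,33.9,24.2,50.2,0.081,-0.924
lecithin_P5,62.2,4.5,39.3,36.9,21.5,53.8,0.072,-0.929
lecithin_P6,62.0,4.5,37.6,35.8,21.6,50.5,0.073,-0.879
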
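system,loop1,loop2,loop3
azolectin,67.10,79.44,82.39
azolectin_P2,38.79,67.68,69.82
azolectin_P4,41.91,62.92,67.46
azolectin_P5,48.96,59.66,63.03
azolectin_P6,46.89,62.58,67.53
lecithin,52.42,75.62,44.45
lecithin_P2,44.15,69.94,72.81
lecithin_P4,28.99,68.76,71.92
lecithin_P5,43.79,70.83,74.74
lecithin_P6,50.09,70.23,73.50
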
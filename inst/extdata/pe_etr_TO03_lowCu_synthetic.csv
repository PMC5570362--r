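replicate_id,rate_type,E_umol_quanta_m2_s,rate,rate_units
1,ETR,2,5.0543,mol_e_per_mol_RCII_s
1,ETR,10,22.8739,mol_e_per_mol_RCII_s
1,ETR,25,58.9709,mol_e_per_mol_RCII_s
1,ETR,50,113.3525,mol_e_per_mol_RCII_s
1,ETR,80,162.386,mol_e_per_mol_RCII_s
1,ETR,120,200.9804,mol_e_per_mol_RCII_s
1,ETR,180,250.4624,mol_e_per_mol_RCII_s
1,ETR,260,243.1688,mol_e_per_mol_RCII_s
1,ETR,380,273.72,mol_e_per_mol_RCII_s
1,ETR,520,246.9995,mol_e_per_mol_RCII_s
1,ETR,700,264.5055,mol_e_per_mol_RCII_s
2,ETR,2,5.2911,mol_e_per_mol_RCII_s
2,ETR,10,21.9504,mol_e_per_mol_RCII_s
2,ETR,25,57.1082,mol_e_per_mol_RCII_s
2,ETR,50,109.0922,mol_e_per_mol_RCII_s
2,ETR,80,164.278,mol_e_per_mol_RCII_s
2,ETR,120,199.1983,mol_e_per_mol_RCII_s
2,ETR,180,203.3462,mol_e_per_mol_RCII_s
2,ETR,260,216.2565,mol_e_per_mol_RCII_s
2,ETR,380,264.3279,mol_e_per_mol_RCII_s
2,ETR,520,244.0054,mol_e_per_mol_RCII_s
2,ETR,700,226.6832,mol_e_per_mol_RCII_s
3,ETR,2,4.679,mol_e_per_mol_RCII_s
3,ETR,10,25.0022,mol_e_per_mol_RCII_s
3,ETR,25,63.6657,mol_e_per_mol_RCII_s
3,ETR,50,107.4834,mol_e_per_mol_RCII_s
3,ETR,80,157.1026,mol_e_per_mol_RCII_s
3,ETR,120,184.9999,mol_e_per_mol_RCII_s
3,ETR,180,237.6354,mol_e_per_mol_RCII_s
3,ETR,260,236.6279,mol_e_per_mol_RCII_s
3,ETR,380,253.1437,mol_e_per_mol_RCII_s
3,ETR,520,256.663,mol_e_per_mol_RCII_s
3,ETR,700,260.9618,mol_e_per_mol_RCII_s
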
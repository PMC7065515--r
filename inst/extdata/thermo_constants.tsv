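# Standard-state thermodynamic properties of aqueous species at 25 C, 1 bar.
# dGf: standard Gibbs free energy of formation, kJ/mol
# dHf: standard enthalpy of formation, kJ/mol
# Aqueous species use the hypothetical 1 mol/L ideal-dilute standard state;
# H2O(l) is the pure-liquid standard state; H+ is the conventional zero.
# Source: Amend AA & Shock EL (2001) Energetics of overall metabolic reactions
# of thermophilic and hyperthermophilic Archaea and Bacteria. FEMS Microbiol
# Rev 25:175-243, Table 4 (values consistent with SUPCRT92/slop98).
# version: 1
species	dGf_kJ_mol	dHf_kJ_mol
NH4+	-79.45	-133.26
O2(aq)	16.54	-12.24
NO3-	-110.91	-206.81
H+	0.0	0.0
H2O(l)	-237.18	-285.83
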
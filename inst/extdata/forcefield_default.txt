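# Default stepwise force-field parameter set (version 1).
# Distances in Angstrom, energies/temperatures in reduced units (k = 1).
ff_version = 1

# bond / pseudo-bond window relative half-widths
bond_halfwidth = 0.02
pseudo_halfwidth = 0.05

# steric core diameters by bead-kind pair: 95% of the closest approach
# observed over dense torsion sampling of the allowed (left half-plane)
# basins, so no legitimate backbone motion is sterically blocked
sigma_N_N = 2.75
sigma_N_CA = 2.8
sigma_N_C = 2.1
sigma_N_CB = 1.8
sigma_CA_CA = 3.8
sigma_CA_C = 3.05
sigma_CA_CB = 2.7
sigma_C_C = 3.0
sigma_C_CB = 2.05
sigma_CB_CB = 2.1
local_sigma_scale = 0.88

# generic nonbonded attractive shell (nonlocal pairs)
nb_well_width = 1.0
nb_well_depth = 0.05

# optional CB-CB hydrophobic well (per-residue scale via hscale_<aa>)
cb_well_r = 6.0
cb_well_depth = 0.0

# i -> i+4 backbone hydrogen-bond well, CA(i)-CA(i+4) gate, and the
# chirality gate CB(i)-CA(i+3) (CA(i+1)-CA(i+3) fallback for Gly acceptors);
# windows centred on the ideal right-handed alpha-helix distances
hb_eps = 3.5

# unconditional square wells inside member windows: per-torsion helical bias
# (C-C / N-N gate pairs) and i -> i+4 contact well (C-N pair)
hb_torsion_well = 0.7
hb_chiral_torsion_well = 0.5
hb_contact_well = 0.3
hb_d_on = 3.95
hb_d_off = 4.65
hb_gate14_lo = 5.9
hb_gate14_hi = 6.95
hb_gate_chi_lo = 6.0
hb_gate_chi_hi = 7.1
hb_gate13_lo = 5.1
hb_gate13_hi = 5.85

# Andersen thermostat heat-exchange factor
hex = 0.1

# helix-propensity weights, w(Ala) = 1
w_A = 1.00
w_C = 0.51
w_D = 0.50
w_E = 0.67
w_F = 0.58
w_G = 0.37
w_H = 0.54
w_I = 0.66
w_K = 0.77
w_L = 0.81
w_M = 0.79
w_N = 0.52
w_P = 0.04
w_Q = 0.68
w_R = 0.81
w_S = 0.61
w_T = 0.52
w_V = 0.54
w_W = 0.61
w_Y = 0.59
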
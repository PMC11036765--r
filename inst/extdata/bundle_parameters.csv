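# Per-bundle one-dimensional ligament element parameters for the default knee.
# k_N: linear-region stiffness, N per unit strain.
# reference_strain: pre-strain at the full-extension reference pose
#   (slack length L0 = Lr / (1 + reference_strain)).
# eps_l: toe-to-linear transition strain of the piecewise force law.
# ACL stiffness follows tensile tests of the human ACL; cruciate/collateral
# reference strains follow the standard 1D ligament-element parameter sets
# used in rigid-body knee models.  The AM = 6%, PL = 10% pairing of the two
# ACL pre-strains is inferred from the bundles' reported flexion behaviour
# (near-isometric AM, PL slackening with flexion), not an explicit statement;
# swap the two values to explore the alternative assignment.
bundle,k_N,reference_strain,eps_l
ACL-AM,5000,0.06,0.03
ACL-PL,5000,0.10,0.03
PCL-AL,9000,-0.24,0.03
PCL-PM,9000,-0.03,0.03
MCL-A,2750,0.02,0.03
MCL-C,2750,0.02,0.03
MCL-P,2750,0.02,0.03
LCL-A,2000,0.02,0.03
LCL-C,2000,0.02,0.03
LCL-P,2000,0.02,0.03
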
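# Region definitions for the human placental aromatase monomer (CYP19A1),
# for use with assign_regions()/region_layer_report() on that structure.
#
# heme / substrate: by residue name (HEM, ASD = androstenedione).
# access_channel / e_site / p_site: published residue lists.
# catalytic_cleft: left empty on purpose -- the fallback rule selects
#   residues with any heavy atom within cleft_distance of the substrate.
# proximal_cavity: APPROXIMATE list spanning the helix-C / H' segments and
#   the K''-L loop region around the heme-ligating Cys437; the exact
#   published average used an unprinted list, so override this for any
#   quantitative comparison.

heme:
  resid: HEM
substrate:
  resid: ASD
catalytic_cleft: {}
access_channel:
  resno: [192, 217, 218, 221, 222, 225, 308, 309, 310, 312, 313, 369,
          474, 478, 479, 480, 481, 482, 483, 484]
proximal_cavity:
  resno: [145, 146, 147, 148, 149, 150, 151, 152,
          348, 349, 350, 351, 352, 353, 354,
          414, 415, 416, 417, 418, 419, 420, 421, 422, 423, 424, 425,
          426, 427, 428, 429, 430, 431, 432, 433, 434, 435, 437, 440]
e_site:
  resno: [177, 186, 197, 209, 210, 222, 482, 483, 489]
p_site:
  resno: [142, 145, 352, 375, 440, 448]
layer_radii: [15, 20]
cleft_distance: 4.5
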
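# Marker-gene roster for the nitrogen cycle.  Each step lists gene
# families; a gene belongs to exactly one step.  Real surveys detect
# additional cycle genes -- edit or extend freely; the `nitrite_to_n2`
# branch pools the denitrification steps from nitrite to dinitrogen.
name: nitrogen_cycle
steps:
  nitrogen_fixation: [nifH, nifD, nifK]
  nitrification: [amoA, amoB, amoC, hao, nxrA, nxrB]
  dissimilatory_nitrate_reduction: [narG, narH, narI, napA, napB]
  dnra: [nrfA, nrfH]
  denitrification: [nirK, nirS, norB, norC, nosZ]
  assimilatory_nitrate_reduction: [nasA, nirA, nirB, nirD]
  ammonia_assimilation: [glnA, gltB, gltD, gdhA]
  urea_hydrolysis: [ureA, ureB, ureC]
branches:
  nitrite_to_n2: [nirK, nirS, norB, norC, nosZ]
  nitrification: [amoA, amoB, amoC, hao, nxrA, nxrB]
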
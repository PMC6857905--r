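# Default species-trait table (synthetic defaults).
# Coral rows: morphology_m (dimensionless cover-to-deposition adjustment),
#   density_d (skeletal bulk density, g cm-3), growth_g (vertical extension,
#   cm yr-1); brc is empty.
# Parrotfish rows: brc (bite-rate constant, dimensionless); coral columns empty.
# Provenance: representative literature-scale values assembled for this
#   package (Indo-Pacific skeletal densities ~1.3-1.6 g cm-3; extension
#   ~0.6-2 cm yr-1 for massive/encrusting forms, faster for acroporids).
#   They are editable stand-ins, not measurements: replace with
#   locally calibrated values for real analyses. brc values are unpublished
#   in the source literature; 20 is the documented package default.
taxon,morphology_m,density_d,growth_g,brc
Porites_rus,0.8,1.40,1.2,
Porites_cylindrica,0.7,1.30,2.0,
Porites_lobata,1.0,1.36,1.1,
Porites_lichen,0.9,1.35,1.0,
Porites_massive,1.0,1.36,1.1,
Montipora_encrusting,1.0,1.51,0.6,
Acropora_hyacinthus,0.6,1.49,5.0,
Acropora_branching,0.5,1.49,7.0,
Goniastrea_retiformis,1.0,1.45,0.9,
Pocillopora_damicornis,0.7,1.46,2.5,
Favites_abdita,1.0,1.45,0.8,
Chlorurus_sordidus,,,,20
Chlorurus_microrhinos,,,,12
Scarus_psittacus,,,,22
Scarus_rubroviolaceus,,,,15
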
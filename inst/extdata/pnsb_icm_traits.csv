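species,state,architecture
Rhodospirillum_rubrum,nonrestricted,vesicular
Rhodospirillum_centenum,nonrestricted,lamellar
Rhodobacter_sphaeroides,nonrestricted,vesicular
Rhodobacter_capsulatus,nonrestricted,vesicular
Rhodovulum_sulfidophilum,nonrestricted,vesicular
Rhodoblastus_acidophilus,nonrestricted,lamellar
Rhodobium_orientis,nonrestricted,lamellar
Rhodomicrobium_vannielii,restricted,lamellar
Afifella_marina,restricted,lamellar
Afifella_pfennigii,restricted,lamellar
Rhodoplanes_elegans,restricted,lamellar
Rhodoplanes_piscinae,restricted,lamellar
Rhodoplanes_roseus,restricted,lamellar
Rhodopseudomonas_palustris,restricted,lamellar
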
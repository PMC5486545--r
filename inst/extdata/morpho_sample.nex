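#NEXUS
[ six taxa, four morphological characters, states labelled 1-3 ]
BEGIN CHARACTERS;
  DIMENSIONS NTAX=6 NCHAR=4;
  FORMAT DATATYPE=STANDARD SYMBOLS="123" MISSING=? GAP=-;
  MATRIX
    arctic_carnivore    11
    temperate_carnivore 11
    tropical_carnivore  11
    arctic_herbivore    22
    temperate_herbivore 22
    tropical_herbivore  2?
    arctic_carnivore    11
    temperate_carnivore 22
    tropical_carnivore  33
    arctic_herbivore    11
    temperate_herbivore 22
    tropical_herbivore  3-
  ;
END;
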
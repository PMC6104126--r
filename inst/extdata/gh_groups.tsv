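family_id	group
GH13	starch
GH15	starch
GH31	starch
GH57	starch
GH1	plant_structural_polysaccharides
GH3	plant_structural_polysaccharides
GH5	plant_structural_polysaccharides
GH6	plant_structural_polysaccharides
GH8	plant_structural_polysaccharides
GH9	plant_structural_polysaccharides
GH10	plant_structural_polysaccharides
GH11	plant_structural_polysaccharides
GH12	plant_structural_polysaccharides
GH26	plant_structural_polysaccharides
GH44	plant_structural_polysaccharides
GH45	plant_structural_polysaccharides
GH48	plant_structural_polysaccharides
GH51	plant_structural_polysaccharides
GH54	plant_structural_polysaccharides
GH62	plant_structural_polysaccharides
GH74	plant_structural_polysaccharides
GH18	chitin
GH19	chitin
GH20	chitin
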
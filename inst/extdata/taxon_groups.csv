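taxon,group_label
Naumann's elephant,proboscideans
Pleistocene elephant fossil,proboscideans
Asian elephant,proboscideans
Human,human
Macaque,medium_primates
Leporid,lagomorphs
Rabbit,lagomorphs
Wild boar,medium_artiodactyls
Sika deer,medium_artiodactyls
Ancient sika deer,medium_artiodactyls
Reindeer,medium_artiodactyls
Japanese serow,medium_artiodactyls
Yabe's giant deer,large_artiodactyls
Cattle,large_artiodactyls
Bison,large_artiodactyls
Japanese marten,medium_carnivores
Dog,medium_carnivores
Raccoon dog,medium_carnivores
Red fox,medium_carnivores
Leopard,medium_carnivores
Brown bear,large_carnivores
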
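(((Cycas_revoluta:0.15,Zamia_furfuracea:0.15):0.15,Ginkgo_biloba:0.30):0.15,(((Cedrus_deodara:0.18,(Abies_firma:0.15,(Picea_smithiana:0.12,Pinus_armandii:0.12):0.06):0.06):0.24,(Ephedra_przewalskii:0.36,(Welwitschia_mirabilis:0.30,Gnetum_montanum:0.30):0.12):0.24):0.12,((Podocarpus_macrophyllus:0.24,Araucaria_cunninghamii:0.24):0.09,(Sciadopitys_verticillata:0.27,((Cephalotaxus_sinensis:0.15,Taxus_cuspidata:0.15):0.09,(Cunninghamia_lanceolata:0.18,(Taiwania_cryptomerioides:0.15,(Metasequoia_glyptostroboides:0.12,Platycladus_orientalis:0.12):0.06):0.06):0.09):0.06):0.09):0.15):0.15);
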
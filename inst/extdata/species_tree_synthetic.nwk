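(Bothriocyrtum_californicum,((Kukulkania_hibernalis,Diguetia_canities),((Euprosthenops_australis,Agelenopsis_aperta),((Deinopis_spinosa,Uloborus_diversus),((Latrodectus_hesperus,Latrodectus_geometricus),((Nephila_clavipes,(Nephila_inaurata,Nephila_clavata)),((Araneus_ventricosus,Metepeira_grandiosa),((Argiope_argentata,Argiope_bruennichi),Argiope_trifasciata))))))));
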
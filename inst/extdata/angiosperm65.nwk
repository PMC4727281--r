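(Amborella_trichopoda,((Spirodela_polyrhiza,(Dioscorea_rotundata,((Phalaenopsis_equestris,Asparagus_officinalis),((Phoenix_dactylifera,Elaeis_guineensis),(Musa_acuminata,(Oryza_sativa,(Brachypodium_distachyon,((Sorghum_bicolor,Zea_mays),Setaria_italica)))))))),(Aquilegia_coerulea,(Nelumbo_nucifera,((Vitis_vinifera,(((((Medicago_truncatula,Lotus_japonicus),(Cicer_arietinum,(Cajanus_cajan,(Glycine_max,(Phaseolus_vulgaris,Vigna_radiata))))),((Morus_notabilis,(Fragaria_vesca,Prunus_persica)),((Cucumis_sativus,Cucumis_melo),Citrullus_lanatus))),(Linum_usitatissimum,((Manihot_esculenta,(Ricinus_communis,Jatropha_curcas)),(Populus_trichocarpa,Salix_purpurea)))),(Eucalyptus_grandis,((Carica_papaya,(((Arabidopsis_thaliana,Arabidopsis_lyrata),Capsella_rubella),(Brassica_rapa,Eutrema_salsugineum))),((Theobroma_cacao,Gossypium_raimondii),Citrus_sinensis))))),((Beta_vulgaris,Dianthus_caryophyllus),((Actinidia_chinensis,Vaccinium_macrocarpon),((Coffea_canephora,((Ipomoea_nil,(Petunia_axillaris,((Nicotiana_tabacum,Nicotiana_sylvestris),(Capsicum_annuum,(Solanum_lycopersicum,Solanum_tuberosum))))),(Olea_europaea,(Mimulus_guttatus,(Sesamum_indicum,(Utricularia_gibba,Dorcoceras_hygrometricum)))))),((Helianthus_annuus,Lactuca_sativa),Daucus_carota)))))))));
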
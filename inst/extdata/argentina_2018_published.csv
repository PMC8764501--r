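block,measure,site,sex,level,n,paf_pct
cell,deaths,all_sites,M,all,1166,16
cell,deaths,all_sites,M,light,167,2
cell,deaths,all_sites,M,moderate,573,8
cell,deaths,all_sites,M,heavy,426,6
cell,deaths,oral_pharynx,M,all,236,40
cell,deaths,oral_pharynx,M,light,39,7
cell,deaths,oral_pharynx,M,moderate,103,17
cell,deaths,oral_pharynx,M,heavy,95,16
cell,deaths,esophagus,M,all,533,46
cell,deaths,esophagus,M,light,128,11
cell,deaths,esophagus,M,moderate,242,21
cell,deaths,esophagus,M,heavy,164,14
cell,deaths,colorectal,M,all,260,7
cell,deaths,colorectal,M,light,0,0
cell,deaths,colorectal,M,moderate,168,4
cell,deaths,colorectal,M,heavy,92,2
cell,deaths,liver,M,all,29,3
cell,deaths,liver,M,light,0,0
cell,deaths,liver,M,moderate,0,0
cell,deaths,liver,M,heavy,29,3
cell,deaths,larynx,M,all,109,17
cell,deaths,larynx,M,light,0,0
cell,deaths,larynx,M,moderate,62,10
cell,deaths,larynx,M,heavy,47,7
cell,deaths,all_sites,F,all,221,2
cell,deaths,all_sites,F,light,63,0.6
cell,deaths,all_sites,F,moderate,139,1
cell,deaths,all_sites,F,heavy,19,0.2
cell,deaths,oral_pharynx,F,all,14,5
cell,deaths,oral_pharynx,F,light,0,0
cell,deaths,oral_pharynx,F,moderate,12,4
cell,deaths,oral_pharynx,F,heavy,3,1
cell,deaths,breast,F,all,155,3
cell,deaths,breast,F,light,63,1
cell,deaths,breast,F,moderate,84,1
cell,deaths,breast,F,heavy,8,0.1
cell,deaths,esophagus,F,all,46,8
cell,deaths,esophagus,F,light,0,0
cell,deaths,esophagus,F,moderate,40,7
cell,deaths,esophagus,F,heavy,8,1
cell,deaths,colorectal,F,all,0,0
cell,deaths,colorectal,F,light,0,0
cell,deaths,colorectal,F,moderate,0,0
cell,deaths,colorectal,F,heavy,0,0
cell,deaths,liver,F,all,4,0.5
cell,deaths,liver,F,light,0,0
cell,deaths,liver,F,moderate,0,0
cell,deaths,liver,F,heavy,4,0.5
cell,deaths,larynx,F,all,4,3
cell,deaths,larynx,F,light,0,0
cell,deaths,larynx,F,moderate,4,3
cell,deaths,larynx,F,heavy,0,0
cell,dalys,all_sites,M,all,18903,16
cell,dalys,all_sites,M,light,2911,2
cell,dalys,all_sites,M,moderate,9177,8
cell,dalys,all_sites,M,heavy,6815,6
cell,dalys,oral_pharynx,M,all,4478,39
cell,dalys,oral_pharynx,M,light,800,7
cell,dalys,oral_pharynx,M,moderate,1912,17
cell,dalys,oral_pharynx,M,heavy,1767,15
cell,dalys,esophagus,M,all,8126,46
cell,dalys,esophagus,M,light,2111,12
cell,dalys,esophagus,M,moderate,3600,20
cell,dalys,esophagus,M,heavy,2415,14
cell,dalys,colorectal,M,all,4095,6
cell,dalys,colorectal,M,light,0,0
cell,dalys,colorectal,M,moderate,2658,4
cell,dalys,colorectal,M,heavy,1437,2
cell,dalys,liver,M,all,436,3
cell,dalys,liver,M,light,0,0
cell,dalys,liver,M,moderate,0,0
cell,dalys,liver,M,heavy,436,3
cell,dalys,larynx,M,all,1768,16
cell,dalys,larynx,M,light,0,0
cell,dalys,larynx,M,moderate,1007,9
cell,dalys,larynx,M,heavy,761,7
cell,dalys,all_sites,F,all,5038,2
cell,dalys,all_sites,F,light,1621,0.7
cell,dalys,all_sites,F,moderate,2878,1
cell,dalys,all_sites,F,heavy,538,0.2
cell,dalys,oral_pharynx,F,all,275,5
cell,dalys,oral_pharynx,F,light,0,0
cell,dalys,oral_pharynx,F,moderate,218,4
cell,dalys,oral_pharynx,F,heavy,57,1
cell,dalys,breast,F,all,3801,3
cell,dalys,breast,F,light,1621,1
cell,dalys,breast,F,moderate,1930,1
cell,dalys,breast,F,heavy,250,0.2
cell,dalys,esophagus,F,all,799,8
cell,dalys,esophagus,F,light,0,0
cell,dalys,esophagus,F,moderate,665,7
cell,dalys,esophagus,F,heavy,134,1
cell,dalys,colorectal,F,all,0,0
cell,dalys,colorectal,F,light,0,0
cell,dalys,colorectal,F,moderate,0,0
cell,dalys,colorectal,F,heavy,0,0
cell,dalys,liver,F,all,97,0.7
cell,dalys,liver,F,light,0,0
cell,dalys,liver,F,moderate,0,0
cell,dalys,liver,F,heavy,97,0.7
cell,dalys,larynx,F,all,66,3
cell,dalys,larynx,F,light,0,0
cell,dalys,larynx,F,moderate,66,3
cell,dalys,larynx,F,heavy,0,0
summary,,total_deaths_2018,,,334514,
summary,,cancer_deaths,,,60764,
summary,,cancer_deaths_pct_total,,,18,
summary,,six_site_deaths,,,18255,
summary,,six_site_deaths_pct_total,,,5,
summary,,attrib_deaths,,,1387,
summary,,attrib_deaths_pct_six_site,,,7.6,
summary,,attrib_deaths_pct_all_cancer,,,2.3,
summary,,attrib_deaths_men,,,1166,
summary,,attrib_deaths_men_pct_six_site,,,16,
summary,,attrib_deaths_men_pct_all_cancer,,,3.7,
summary,,attrib_deaths_women,,,221,
summary,,attrib_deaths_women_pct_six_site,,,2,
summary,,attrib_deaths_women_pct_all_cancer,,,0.8,
summary,,moderate_attrib_deaths,,,713,
summary,,moderate_attrib_deaths_pct,,,51,
summary,,cancer_dalys,,,1137397,
summary,,attrib_dalys,,,23948,
summary,,attrib_dalys_pct_six_site,,,7,
summary,,attrib_dalys_pct_all_cancer,,,2.1,
summary,,attrib_dalys_men,,,18904,
summary,,attrib_dalys_women,,,5045,
summary,,moderate_attrib_dalys,,,12059,
summary,,moderate_attrib_dalys_pct,,,50,
summary,,extended_extra_attrib_deaths,,,186,
summary,,extended_extra_attrib_dalys,,,2677,
summary,,heavy_to_moderate_prevented_deaths,,,338,
summary,,heavy_to_moderate_prevented_dalys,,,5498,
summary,,heavy_to_moderate_pct_deaths,,,24,
summary,,heavy_to_moderate_pct_dalys,,,23,
summary,,moderate_to_light_prevented_deaths,,,639,
summary,,moderate_to_light_prevented_dalys,,,10853,
summary,,moderate_to_light_pct_deaths,,,46,
summary,,moderate_to_light_pct_dalys,,,45,
summary,,combined_extra_prevented_deaths,,,105,
summary,,combined_extra_prevented_dalys,,,4523,
summary,,combined_pct_deaths,,,54,
summary,,combined_pct_dalys,,,64,
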
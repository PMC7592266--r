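inn,route,strength,strength_unit,units_per_pack,packs_sold,quarter
asparaginase,intramuscular,10000,active_units,5,518,2017-Q1
asparaginase,intramuscular,10000,active_units,5,518,2017-Q2
asparaginase,intramuscular,10000,active_units,5,518,2017-Q3
asparaginase,intramuscular,10000,active_units,5,519,2017-Q4
mercaptopurine,oral,50,mg,5,17002,2017-Q1
mercaptopurine,oral,50,mg,5,17002,2017-Q2
mercaptopurine,oral,50,mg,5,17002,2017-Q3
mercaptopurine,oral,50,mg,5,17001,2017-Q4
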
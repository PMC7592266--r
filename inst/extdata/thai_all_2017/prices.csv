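inn,route,smallest_unit_strength,unit_price_usd,price_year
asparaginase,intramuscular,10000,49.0225743433905,2017
methotrexate,intravenous,50, 2.2885068526088,2017
methotrexate,oral,2.5,0.082051260232475,2017
methotrexate,intrathecal,10,0.503417533432392,2017
mercaptopurine,oral,50,0.735177918667031,2017
cytarabine,intravenous,100,3.89166887066914,2017
vincristine,intravenous,1,4.05857282727639,2017
tioguanine,oral,40,2.21237797016025,2017
mitoxantrone,intravenous,10,103.446428571429,2017
doxorubicin,intravenous,10,2.85357247868274,2017
cyclophosphamide,intravenous,500,4.72655122655123,2017
etoposide,intravenous,100,           5.632,2017
leucovorin,intravenous,30,6.11692844677138,2017
mesna,intravenous,400,3.12043795620438,2017
prednisolone,oral,5,0.0101789929189614,2017
dexamethasone,oral,2,0.0140155834283542,2017
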
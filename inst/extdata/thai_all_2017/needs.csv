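inn,route,unit_kind,scope,total_amount,total_lb,total_ub,smallest_units,units_lb,units_ub
asparaginase,intramuscular,active_units,diagnosed,46070000,28540220.1258,62875408.805,4607,2854.022,6287.5409
methotrexate,intravenous,mg,diagnosed,4159000,2576487.4214,5676119.4969,83180,51529.7484,113522.3899
methotrexate,oral,mg,diagnosed,587590,364010.1572,801931.0063,235036,145604.0629,320772.4025
methotrexate,intrathecal,mg,diagnosed,67300,41692.1384,91849.6855,6730,4169.2138,9184.9686
mercaptopurine,oral,mg,diagnosed,11175050,6922908.3333,15251483.3333,223501,138458.1667,305029.6667
cytarabine,intravenous,mg,diagnosed,1890500,1171158.805,2580116.3522,18905,11711.5881,25801.1635
vincristine,intravenous,mg,diagnosed,17363,10756.3239,23696.673,17363,10756.3239,23696.673
tioguanine,oral,mg,diagnosed,217160,134529.9371,296375.5975,5429,3363.2484,7409.3899
mitoxantrone,intravenous,mg,diagnosed,1120,693.8365,1528.5535,112,69.3836,152.8553
doxorubicin,intravenous,mg,diagnosed,34010,21069.0881,46416.1635,3401,2106.9088,4641.6164
cyclophosphamide,intravenous,mg,diagnosed,693000,429311.3208,945792.4528,1386,858.6226,1891.5849
etoposide,intravenous,mg,diagnosed,37500,23231.1321,51179.2453,375,232.3113,511.7925
leucovorin,intravenous,mg,diagnosed,103140,63894.9057,140763.3962,3438,2129.8302,4692.1132
mesna,intravenous,mg,diagnosed,328800,203690.566,448739.6226,822,509.2264,1121.8491
prednisolone,oral,mg,diagnosed,915120,566913.9623,1248937.3585,183024,113382.7925,249787.4717
dexamethasone,oral,mg,diagnosed,42096,26078.3396,57451.7736,21048,13039.1698,28725.8868
asparaginase,intramuscular,active_units,diagnosed_plus_undiagnosed,77190000,42867242.0263,115133302.0638,7719,4286.7242,11513.3302
methotrexate,intravenous,mg,diagnosed_plus_undiagnosed,6968200,3869769.606,10393469.0432,139364,77395.3921,207869.3809
methotrexate,oral,mg,diagnosed_plus_undiagnosed,984495,546736.4353,1468430.6285,393798,218694.5741,587372.2514
methotrexate,intrathecal,mg,diagnosed_plus_undiagnosed,112810,62648.7054,168262.5704,11281,6264.8705,16826.257
mercaptopurine,oral,mg,diagnosed_plus_undiagnosed,18723600,10398096.8105,27927320.8255,374472,207961.9362,558546.4165
cytarabine,intravenous,mg,diagnosed_plus_undiagnosed,3167400,1759006.379,4724358.349,31674,17590.0638,47243.5835
vincristine,intravenous,mg,diagnosed_plus_undiagnosed,29092,16156.1576,43392.3827,29092,16156.1576,43392.3827
tioguanine,oral,mg,diagnosed_plus_undiagnosed,363840,202057.4859,542688.1801,9096,5051.4371,13567.2045
mitoxantrone,intravenous,mg,diagnosed_plus_undiagnosed,1880,1044.0525,2804.1276,188,104.4053,280.4128
doxorubicin,intravenous,mg,diagnosed_plus_undiagnosed,56980,31643.6773,84988.9306,5698,3164.3677,8498.8931
cyclophosphamide,intravenous,mg,diagnosed_plus_undiagnosed,1161000,644757.9737,1731697.9362,2322,1289.5159,3463.3959
etoposide,intravenous,mg,diagnosed_plus_undiagnosed,62800,34875.7974,93669.7936,628,348.758,936.6979
leucovorin,intravenous,mg,diagnosed_plus_undiagnosed,172830,95980.6379,257785.8349,5761,3199.3546,8592.8612
mesna,intravenous,mg,diagnosed_plus_undiagnosed,551200,306107.3171,822146.3415,1378,765.2683,2055.3659
prednisolone,oral,mg,diagnosed_plus_undiagnosed,1533270,851497.0356,2286959.9437,306654,170299.4071,457391.9887
dexamethasone,oral,mg,diagnosed_plus_undiagnosed,70530,39168.6304,105199.531,35265,19584.3152,52599.7655
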
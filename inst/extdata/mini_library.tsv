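guide_id	gene_id	category
TGT01_sg01	TGT01	gene
TGT01_sg02	TGT01	gene
TGT01_sg03	TGT01	gene
TGT01_sg04	TGT01	gene
TGT01_sg05	TGT01	gene
TGT01_sg06	TGT01	gene
TGT01_sg07	TGT01	gene
TGT01_sg08	TGT01	gene
TGT01_sg09	TGT01	gene
TGT01_sg10	TGT01	gene
TGT02_sg01	TGT02	gene
TGT02_sg02	TGT02	gene
TGT02_sg03	TGT02	gene
TGT02_sg04	TGT02	gene
TGT02_sg05	TGT02	gene
TGT02_sg06	TGT02	gene
TGT02_sg07	TGT02	gene
TGT02_sg08	TGT02	gene
TGT02_sg09	TGT02	gene
TGT02_sg10	TGT02	gene
TGT03_sg01	TGT03	gene
TGT03_sg02	TGT03	gene
TGT03_sg03	TGT03	gene
TGT03_sg04	TGT03	gene
TGT03_sg05	TGT03	gene
TGT03_sg06	TGT03	gene
TGT03_sg07	TGT03	gene
TGT03_sg08	TGT03	gene
TGT03_sg09	TGT03	gene
TGT03_sg10	TGT03	gene
TGT04_sg01	TGT04	gene
TGT04_sg02	TGT04	gene
TGT04_sg03	TGT04	gene
TGT04_sg04	TGT04	gene
TGT04_sg05	TGT04	gene
TGT04_sg06	TGT04	gene
TGT04_sg07	TGT04	gene
TGT04_sg08	TGT04	gene
TGT04_sg09	TGT04	gene
TGT04_sg10	TGT04	gene
TGT05_sg01	TGT05	gene
TGT05_sg02	TGT05	gene
TGT05_sg03	TGT05	gene
TGT05_sg04	TGT05	gene
TGT05_sg05	TGT05	gene
TGT05_sg06	TGT05	gene
TGT05_sg07	TGT05	gene
TGT05_sg08	TGT05	gene
TGT05_sg09	TGT05	gene
TGT05_sg10	TGT05	gene
TGT06_sg01	TGT06	gene
TGT06_sg02	TGT06	gene
TGT06_sg03	TGT06	gene
TGT06_sg04	TGT06	gene
TGT06_sg05	TGT06	gene
TGT06_sg06	TGT06	gene
TGT06_sg07	TGT06	gene
TGT06_sg08	TGT06	gene
TGT06_sg09	TGT06	gene
TGT06_sg10	TGT06	gene
TGT07_sg01	TGT07	gene
TGT07_sg02	TGT07	gene
TGT07_sg03	TGT07	gene
TGT07_sg04	TGT07	gene
TGT07_sg05	TGT07	gene
TGT07_sg06	TGT07	gene
TGT07_sg07	TGT07	gene
TGT07_sg08	TGT07	gene
TGT07_sg09	TGT07	gene
TGT07_sg10	TGT07	gene
TGT08_sg01	TGT08	gene
TGT08_sg02	TGT08	gene
TGT08_sg03	TGT08	gene
TGT08_sg04	TGT08	gene
TGT08_sg05	TGT08	gene
TGT08_sg06	TGT08	gene
TGT08_sg07	TGT08	gene
TGT08_sg08	TGT08	gene
TGT08_sg09	TGT08	gene
TGT08_sg10	TGT08	gene
TGT09_sg01	TGT09	gene
TGT09_sg02	TGT09	gene
TGT09_sg03	TGT09	gene
TGT09_sg04	TGT09	gene
TGT09_sg05	TGT09	gene
TGT09_sg06	TGT09	gene
TGT09_sg07	TGT09	gene
TGT09_sg08	TGT09	gene
TGT09_sg09	TGT09	gene
TGT09_sg10	TGT09	gene
TGT10_sg01	TGT10	gene
TGT10_sg02	TGT10	gene
TGT10_sg03	TGT10	gene
TGT10_sg04	TGT10	gene
TGT10_sg05	TGT10	gene
TGT10_sg06	TGT10	gene
TGT10_sg07	TGT10	gene
TGT10_sg08	TGT10	gene
TGT10_sg09	TGT10	gene
TGT10_sg10	TGT10	gene
CTRL_sg0001	control	safe
CTRL_sg0002	control	safe
CTRL_sg0003	control	safe
CTRL_sg0004	control	safe
CTRL_sg0005	control	safe
CTRL_sg0006	control	safe
CTRL_sg0007	control	safe
CTRL_sg0008	control	safe
CTRL_sg0009	control	safe
CTRL_sg0010	control	safe
CTRL_sg0011	control	safe
CTRL_sg0012	control	safe
CTRL_sg0013	control	safe
CTRL_sg0014	control	safe
CTRL_sg0015	control	safe
CTRL_sg0016	control	safe
CTRL_sg0017	control	safe
CTRL_sg0018	control	safe
CTRL_sg0019	control	safe
CTRL_sg0020	control	safe
CTRL_sg0021	control	safe
CTRL_sg0022	control	safe
CTRL_sg0023	control	safe
CTRL_sg0024	control	safe
CTRL_sg0025	control	safe
CTRL_sg0026	control	safe
CTRL_sg0027	control	safe
CTRL_sg0028	control	safe
CTRL_sg0029	control	safe
CTRL_sg0030	control	safe
CTRL_sg0031	control	safe
CTRL_sg0032	control	safe
CTRL_sg0033	control	safe
CTRL_sg0034	control	safe
CTRL_sg0035	control	safe
CTRL_sg0036	control	safe
CTRL_sg0037	control	safe
CTRL_sg0038	control	safe
CTRL_sg0039	control	safe
CTRL_sg0040	control	safe
CTRL_sg0041	control	safe
CTRL_sg0042	control	safe
CTRL_sg0043	control	safe
CTRL_sg0044	control	safe
CTRL_sg0045	control	safe
CTRL_sg0046	control	safe
CTRL_sg0047	control	safe
CTRL_sg0048	control	safe
CTRL_sg0049	control	safe
CTRL_sg0050	control	safe
CTRL_sg0051	control	nontargeting
CTRL_sg0052	control	nontargeting
CTRL_sg0053	control	nontargeting
CTRL_sg0054	control	nontargeting
CTRL_sg0055	control	nontargeting
CTRL_sg0056	control	nontargeting
CTRL_sg0057	control	nontargeting
CTRL_sg0058	control	nontargeting
CTRL_sg0059	control	nontargeting
CTRL_sg0060	control	nontargeting
CTRL_sg0061	control	nontargeting
CTRL_sg0062	control	nontargeting
CTRL_sg0063	control	nontargeting
CTRL_sg0064	control	nontargeting
CTRL_sg0065	control	nontargeting
CTRL_sg0066	control	nontargeting
CTRL_sg0067	control	nontargeting
CTRL_sg0068	control	nontargeting
CTRL_sg0069	control	nontargeting
CTRL_sg0070	control	nontargeting
CTRL_sg0071	control	nontargeting
CTRL_sg0072	control	nontargeting
CTRL_sg0073	control	nontargeting
CTRL_sg0074	control	nontargeting
CTRL_sg0075	control	nontargeting
CTRL_sg0076	control	nontargeting
CTRL_sg0077	control	nontargeting
CTRL_sg0078	control	nontargeting
CTRL_sg0079	control	nontargeting
CTRL_sg0080	control	nontargeting
CTRL_sg0081	control	nontargeting
CTRL_sg0082	control	nontargeting
CTRL_sg0083	control	nontargeting
CTRL_sg0084	control	nontargeting
CTRL_sg0085	control	nontargeting
CTRL_sg0086	control	nontargeting
CTRL_sg0087	control	nontargeting
CTRL_sg0088	control	nontargeting
CTRL_sg0089	control	nontargeting
CTRL_sg0090	control	nontargeting
CTRL_sg0091	control	nontargeting
CTRL_sg0092	control	nontargeting
CTRL_sg0093	control	nontargeting
CTRL_sg0094	control	nontargeting
CTRL_sg0095	control	nontargeting
CTRL_sg0096	control	nontargeting
CTRL_sg0097	control	nontargeting
CTRL_sg0098	control	nontargeting
CTRL_sg0099	control	nontargeting
CTRL_sg0100	control	nontargeting
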
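pt	soc
EVT_0001	General disorders and administration site conditions
EVT_0002	Injury, poisoning and procedural complications
EVT_0003	Gastrointestinal disorders
EVT_0004	Investigations
EVT_0005	Nervous system disorders
EVT_0006	Endocrine disorders
EVT_0007	Cardiac disorders
EVT_0008	Musculoskeletal and connective tissue disorders
EVT_0009	Infections and infestations
EVT_0010	Metabolism and nutrition disorders
EVT_0011	General disorders and administration site conditions
EVT_0012	Injury, poisoning and procedural complications
EVT_0013	Gastrointestinal disorders
EVT_0014	Investigations
EVT_0015	Nervous system disorders
EVT_0016	Endocrine disorders
EVT_0017	Cardiac disorders
EVT_0018	Musculoskeletal and connective tissue disorders
EVT_0019	Infections and infestations
EVT_0020	Metabolism and nutrition disorders
EVT_0021	General disorders and administration site conditions
EVT_0022	Injury, poisoning and procedural complications
EVT_0023	Gastrointestinal disorders
EVT_0024	Investigations
EVT_0025	Nervous system disorders
EVT_0026	Endocrine disorders
EVT_0027	Cardiac disorders
EVT_0028	Musculoskeletal and connective tissue disorders
EVT_0029	Infections and infestations
EVT_0030	Metabolism and nutrition disorders
EVT_0031	General disorders and administration site conditions
EVT_0032	Injury, poisoning and procedural complications
EVT_0033	Gastrointestinal disorders
EVT_0034	Investigations
EVT_0035	Nervous system disorders
EVT_0036	Endocrine disorders
EVT_0037	Cardiac disorders
EVT_0038	Musculoskeletal and connective tissue disorders
EVT_0039	Infections and infestations
EVT_0040	Metabolism and nutrition disorders
EVT_0041	General disorders and administration site conditions
EVT_0042	Injury, poisoning and procedural complications
EVT_0043	Gastrointestinal disorders
EVT_0044	Investigations
EVT_0045	Nervous system disorders
EVT_0046	Endocrine disorders
EVT_0047	Cardiac disorders
EVT_0048	Musculoskeletal and connective tissue disorders
EVT_0049	Infections and infestations
EVT_0050	Metabolism and nutrition disorders
EVT_0051	General disorders and administration site conditions
EVT_0052	Injury, poisoning and procedural complications
EVT_0053	Gastrointestinal disorders
EVT_0054	Investigations
EVT_0055	Nervous system disorders
EVT_0056	Endocrine disorders
EVT_0057	Cardiac disorders
EVT_0058	Musculoskeletal and connective tissue disorders
EVT_0059	Infections and infestations
EVT_0060	Metabolism and nutrition disorders
EVT_0061	General disorders and administration site conditions
EVT_0062	Injury, poisoning and procedural complications
EVT_0063	Gastrointestinal disorders
EVT_0064	Investigations
EVT_0065	Nervous system disorders
EVT_0066	Endocrine disorders
EVT_0067	Cardiac disorders
EVT_0068	Musculoskeletal and connective tissue disorders
EVT_0069	Infections and infestations
EVT_0070	Metabolism and nutrition disorders
EVT_0071	General disorders and administration site conditions
EVT_0072	Injury, poisoning and procedural complications
EVT_0073	Gastrointestinal disorders
EVT_0074	Investigations
EVT_0075	Nervous system disorders
EVT_0076	Endocrine disorders
EVT_0077	Cardiac disorders
EVT_0078	Musculoskeletal and connective tissue disorders
EVT_0079	Infections and infestations
EVT_0080	Metabolism and nutrition disorders
EVT_0081	General disorders and administration site conditions
EVT_0082	Injury, poisoning and procedural complications
EVT_0083	Gastrointestinal disorders
EVT_0084	Investigations
EVT_0085	Nervous system disorders
EVT_0086	Endocrine disorders
EVT_0087	Cardiac disorders
EVT_0088	Musculoskeletal and connective tissue disorders
EVT_0089	Infections and infestations
EVT_0090	Metabolism and nutrition disorders
EVT_0091	General disorders and administration site conditions
EVT_0092	Injury, poisoning and procedural complications
EVT_0093	Gastrointestinal disorders
EVT_0094	Investigations
EVT_0095	Nervous system disorders
EVT_0096	Endocrine disorders
EVT_0097	Cardiac disorders
EVT_0098	Musculoskeletal and connective tissue disorders
EVT_0099	Infections and infestations
EVT_0100	Metabolism and nutrition disorders
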
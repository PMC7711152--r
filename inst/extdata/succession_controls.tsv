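sample_id	otu_001	otu_002	otu_003	otu_004	otu_005	otu_006	otu_007	otu_008	otu_009	otu_010	otu_011	otu_012	otu_013	otu_014	otu_015	otu_016	otu_017	otu_018	otu_019	otu_020	otu_021	otu_022	otu_023	otu_024	otu_025	otu_026	otu_027	otu_028	otu_029	otu_030	otu_031	otu_032	otu_033	otu_034	otu_035	otu_036	otu_037	otu_038	otu_039	otu_040	otu_041	otu_042	otu_043	otu_044	otu_045	otu_046	otu_047	otu_048	otu_049	otu_050	otu_051	otu_052	otu_053	otu_054	otu_055	otu_056	otu_057	otu_058	otu_059	otu_060
control_01	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1102	898
control_02	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1107	893
control_03	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1232	768
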
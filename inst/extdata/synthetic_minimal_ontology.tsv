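sample_id	tissue	neoplastic
S0001	breast	FALSE
S0002	breast	FALSE
S0003	breast	FALSE
S0004	breast	FALSE
S0005	breast	FALSE
S0006	breast	FALSE
S0007	breast	FALSE
S0008	breast	FALSE
S0009	breast	FALSE
S0010	breast	FALSE
S0011	breast	FALSE
S0012	breast	FALSE
S0013	breast	TRUE
S0014	breast	TRUE
S0015	breast	TRUE
S0016	breast	TRUE
S0017	breast	TRUE
S0018	breast	TRUE
S0019	breast	TRUE
S0020	breast	TRUE
S0021	breast	TRUE
S0022	breast	TRUE
S0023	breast	TRUE
S0024	breast	TRUE
S0025	lung	FALSE
S0026	lung	FALSE
S0027	lung	FALSE
S0028	lung	FALSE
S0029	lung	FALSE
S0030	lung	FALSE
S0031	lung	FALSE
S0032	lung	FALSE
S0033	lung	FALSE
S0034	lung	FALSE
S0035	lung	FALSE
S0036	lung	FALSE
S0037	lung	TRUE
S0038	lung	TRUE
S0039	lung	TRUE
S0040	lung	TRUE
S0041	lung	TRUE
S0042	lung	TRUE
S0043	lung	TRUE
S0044	lung	TRUE
S0045	lung	TRUE
S0046	lung	TRUE
S0047	lung	TRUE
S0048	lung	TRUE
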
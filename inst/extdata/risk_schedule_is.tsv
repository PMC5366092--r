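sex	age	risk	index_age	subtype_fraction
female	65	0.018	55	1
female	75	0.054	55	1
female	85	0.121	55	1
male	65	0.024	55	1
male	75	0.073	55	1
male	85	0.126	55	1
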
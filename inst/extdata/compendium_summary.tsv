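dataset	tissue	n_arrays	n_modules
Milano	diffuse skin	75	39
Pendergrass	diffuse skin	89	38
Hinchcliff	diffuse skin	165	62
LSSc	limited skin	24	39
UCL	limited skin	15	98
Christmann	lung	18	56
Bostwick	lung	62	54
ESO	esophagus	33	71
PBMC	pbmc	54	38
Risbano	pbmc	38	54
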
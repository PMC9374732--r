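candidate	relative	relative_name	relationship	phi_exp
Billy	3572	Batari	granddaughter	0.125
Dolly	1387	Dumplin	daughter	0.250
Dennis	1387	Dumplin	daughter	0.250
Louis	3619	Max	grandson	0.125
Likoe	3351	Menari	great-granddaughter	0.063
Sibu	2069	Tengku	son	0.250
Bubbles	1980	Bella	daughter	0.250
Bubbles	1773	Oliver	son	0.250
Bubbles	3450	Nairi/Nadira	granddaughter	0.125
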
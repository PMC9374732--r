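biosample	lab_id
SAMN00007164	KB5404
SAMN00007165	KB4204
SAMN00007166	KB5406
SAMN00007167	KB5405
SAMN00007168	NA
SAMN00007169	KB5883
SAMN00007170	KB9258
SAMN00007171	KB4661
SAMN00007172	KB4361
SAMN00007173	NA
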
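probe_code	at_id	sgn_u	description
LE12J18	At1g00100	SGN-U570001	synthetic annotation: putative aspartate-pathway enzyme
LE13G19	At2g00200	SGN-U570002	synthetic annotation: tropane-alkaloid-related transcript
LE22O03	At3g00300	SGN-U570003	synthetic annotation: glutamate-cycle-related transcript
LE7E01	At4g00400	SGN-U570004	synthetic annotation: example probe for detail views
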
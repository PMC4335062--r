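id	phase	species
P001	f	synthetic
P002	f	synthetic
P003	f	synthetic
P004	f	synthetic
P005	f	synthetic
P006	f	synthetic
P007	f	synthetic
P008	f	synthetic
P009	f	synthetic
P010	f	synthetic
P011	f	synthetic
P012	f	synthetic
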
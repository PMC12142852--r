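taxid	scientific_name	rank	submittable
218034	uncultured Enterobacteriaceae bacterium	species	true
543	Enterobacteriaceae	family	false
77133	uncultured bacterium	species	true
115547	uncultured archaeon	species	true
562	Escherichia coli	species	true
9000001	uncultured Methanococcus sp.	species	true
9000002	uncultured Examplaceae bacterium	species	false
9000003	uncultured bacterium adhaerens	species	true
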
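file	md5
clopidogrel_arginine_modes.tsv	c114c977588e8fbca19e9f40a1e3c802
aspirin_arginine_modes.tsv	86306fde474f03534a6dae20b5e2f20e
biomarker_reference.tsv	8523f47fb4a42ccba0c0c98e09ad413b
aspirin_biomarker_override.tsv	bcf9d2e28930539be1990f99c230d894
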
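name,swiss_label,percepta_label,consensus_reported,derek_flags
Specs AH-487/42478269,non_penetrant,penetrant,penetrant,
Comgenex CGX-3274395,penetrant,weak_penetrant,penetrant,
Chem T&I AMCLME-10390,non_penetrant,penetrant,penetrant,hepatotoxicity:plausible;cardiotoxicity:plausible
Asinex BAS 07211091,non_penetrant,weak_penetrant,non_penetrant,
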
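#PPM n=100
A	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
C	0.85	0.05	0.85	0.85	0.05	0.85	0.85	0.05	0.85	0.85	0.05	0.85	0.85	0.05	0.85	0.85
G	0.05	0.85	0.05	0.05	0.85	0.05	0.05	0.85	0.05	0.05	0.85	0.05	0.05	0.85	0.05	0.05
T	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05	0.05
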
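abbrev	expansion
st	saint
ste	sainte
sts	saints
stes	saintes
sr	sur
s	sur
ss	sous
vx	vieux
gd	grand
gde	grande
pt	petit
pte	petite
nd	notredame
chap	chapelle
chat	chateau
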
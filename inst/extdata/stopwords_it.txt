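# Italian stop words: articles, prepositions, conjunctions, pronouns,
# common auxiliaries. One word per line.
il
lo
la
i
gli
le
un
uno
una
di
a
da
in
con
su
per
tra
fra
del
dello
della
dei
degli
delle
al
allo
alla
ai
agli
alle
dal
dallo
dalla
dai
dagli
dalle
nel
nello
nella
nei
negli
nelle
sul
sullo
sulla
sui
sugli
sulle
e
ed
o
od
ma
se
che
chi
cui
non
come
dove
quando
anche
poi
quindi
mentre
dopo
prima
durante
verso
senza
sopra
sotto
questo
questa
questi
queste
quello
quella
quelli
quelle
suo
sua
suoi
sue
loro
essere
avere
ha
hanno
era
erano
sono
viene
vengono
si
lui
lei
noi
voi
io
tu
ci
vi
ne
piu
meno
molto
poco
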
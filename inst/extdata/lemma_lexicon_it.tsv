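# surface form <TAB> lemma. Dictionary-based fallback lexicon: plural
# nouns to singular, inflected verb forms to infinitive. Forms not listed
# pass through unchanged.
braccia	braccio
bracci	braccio
gambe	gamba
mani	mano
piedi	piede
occhi	occhio
arti	arto
teste	testa
crisi	crisi
scosse	scossa
clonie	clonia
movimenti	movimento
automatismi	automatismo
sguardi	sguardo
simili	simile
simile	simile
precedenti	precedente
precedente	precedente
apre	aprire
aprono	aprire
chiude	chiudere
chiudono	chiudere
solleva	sollevare
sollevano	sollevare
muove	muovere
muovono	muovere
porta	portare
portano	portare
gira	girare
girano	girare
inizia	iniziare
iniziano	iniziare
presenta	presentare
presentano	presentare
mostra	mostrare
mostrano	mostrare
compare	comparire
compaiono	comparire
dura	durare
durano	durare
osserva	osservare
osservano	osservare
fissi	fisso
fissa	fisso
aperti	aperto
aperte	aperto
chiusi	chiuso
chiuse	chiuso
destri	destro
destra	destro
destre	destro
sinistri	sinistro
sinistra	sinistro
sinistre	sinistro
superiori	superiore
inferiori	inferiore
tonici	tonico
tonica	tonico
toniche	tonico
cloniche	clonico
clonici	clonico
secondarie	secondario
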
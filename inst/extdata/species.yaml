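# Model-organism lexicon: canonical species key -> surface lemmas accepted
# as nominal mentions.  Edit or pass a modified copy to detect_organisms().
mouse: [mouse, mice, murine]
zebrafish: [zebrafish]
drosophila: [drosophila, fly, flies]
worm: [worm, elegans, nematode]
yeast: [yeast]
rat: [rat]
xenopus: [xenopus, frog]
rabbit: [rabbit]
pig: [pig, swine]
sheep: [sheep, lamb]
cattle: [cattle, cow, bull, bovine]
chicken: [chicken]
dog: [dog, canine]
monkey: [monkey, macaque]
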
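# Nine built-in phenotype extraction patterns.
# Three syntactic shapes (JJ modifier, ADJP modifier, NP coordination)
# crossed with three entity namespace groups.
p1: NP < (JJ < (SEM < /PATO/) ++ (/NN.?/ < (SEM < /FMA|RXNORM|CHEBI|MA/)))
p2: NP < ((ADJP < (JJ < (SEM < /PATO/))) ++ (/NN.?/ < (SEM < /FMA|RXNORM|CHEBI|MA/)))
p3: NP < ((NP < (JJ < (SEM < /PATO/))) + CC (NP < (NN < (SEM < /FMA|RXNORM|CHEBI|MA/))))
p4: NP < (JJ < (SEM < /PATO/) ++ (/NN.?/ < (SEM < /MP|HP/)))
p5: NP < ((ADJP < (JJ < (SEM < /PATO/))) ++ (/NN.?/ < (SEM < /MP|HP/)))
p6: NP < ((NP < (JJ < (SEM < /PATO/))) + CC (NP < (NN < (SEM < /MP|HP/))))
p7: NP < (JJ < (SEM < /PATO/) ++ (/NN.?/ < (SEM < /DOID|ORDO|OMIM/)))
p8: NP < ((ADJP < (JJ < (SEM < /PATO/))) ++ (/NN.?/ < (SEM < /DOID|ORDO|OMIM/)))
p9: NP < ((NP < (JJ < (SEM < /PATO/))) + CC (NP < (NN < (SEM < /DOID|ORDO|OMIM/))))
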
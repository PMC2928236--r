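species_tree_synthetic.nwk: SYNTHETIC stand-in species tree for the spider
taxa sampled in spidroin terminal-domain studies.  The topology was assembled
from published spider phylogenies at the family level (Mygalomorphae sister
to Araneomorphae; Haplogynae, the RTA clade, Deinopoidea and Araneoidea
nested successively) with genus-level placements following the standard
references for Araneidae, Argiope and Nephila.  It is an input fixture, not
a computed result, and is not a reproduction of any single published figure.
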
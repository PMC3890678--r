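species	n_samples	rbcL_unique	trnH_unique	combined_unique	rbcL_shared	trnH_shared	combined_shared	shared_samples
Cedrus atlantica	3	2	2	2	0	0	0	0
Cedrus deodara	3	1	1	1	0	0	0	0
Cedrus libani	3	1	1	1	0	0	0	0
Crataegus monogyna	3	0	0	0	1	1	1	3
Crataegus oxyacantha	2	0	1	1	1	1	1	1
Crataegus azarolus	4	0	2	2	1	0	0	0
Sorbus aria	3	1	3	3	0	0	0	0
Sorbus aucuparia	2	1	1	1	1	1	1	1
Sorbus domestica	3	0	1	1	1	1	1	1
Sorbus torminalis	3	1	1	1	0	0	0	0
Aesculus hippocastanus	3	1	2	2	0	0	0	0
Aesculus indica	3	1	3	3	0	0	0	0
Fraxinus ornus	5	2	4	5	1	0	0	0
Fraxinus angustifolia	3	0	1	1	1	1	1	1
Fraxinus excelsior	2	0	0	0	1	1	1	2
Sambucus nigra	5	1	4	4	1	0	0	0
Sambucus ebulus	2	1	2	2	1	0	0	0
Sambucus racemosa	1	1	1	1	0	0	0	0
Passiflora incarnata	2	2	2	2	0	0	0	0
Passiflora edulis	1	1	1	1	0	0	0	0
Punica granatum	4	1	1	1	n.d.	n.d.	n.d.	0
Ziziphus jujuba	3	1	1	1	n.d.	n.d.	n.d.	0
Ilex aquifolium	4	0	0	0	1	1	1	4
Ilex latifolia	1	0	0	0	1	1	1	1
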
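species	n_samples	max_intra	min_inter	gap
Cedrus atlantica	3	0.0015	0.0015	0
Cedrus deodara	3	0	0.0015	0.0015
Cedrus libani	3	0	0.0023	0.0023
Sorbus aria	3	0.002898554	0.000950571	-0.0019
Sorbus aucuparia	2	0.0058	0	-0.0058
Sorbus domestica	3	0.0009	0	-0.0009
Sorbus torminalis	3	0	0.0009	0.0009
Crataegus azarolus	3	0.0009	0	-0.0009
Crataegus monogyna	2	0.0019	0	-0.0019
Crataegus oxyacantha	4	0	0	0
Aesculus hippocastanus	3	0	0.0064	0.0064
Aesculus indica	3	0	0.0064	0.0064
Fraxinus ornus	5	0.00568	0.00284	-0.0028
Fraxinus angustifolia	3	0.0036	0	-0.0036
Fraxinus excelsior	2	0	0	0
Sambucus nigra	5	0.0017	0	-0.0017
Sambucus ebulus	2	0.0101	0	-0.0101
Sambucus racemosa	1	n.d.	0.0142	n.d.
Passiflora incarnata	2	0.02397	0.01588	-0.0081
Passiflora edulis	1	n.d.	0.0158	n.d.
Punica granatum	4	0	n.d.	n.d.
Ziziphus jujuba	3	0	n.d.	n.d.
Ilex aquifolium	4	0	0	0
Ilex latifolia	1	n.d.	0	n.d.
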
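species	hap_ok	gap_ok	ref_ok
Cedrus atlantica	yes	no	yes
Cedrus deodara	yes	yes	yes
Cedrus libani	yes	yes	absent
Crataegus monogyna	no	no	no
Crataegus oxyacantha	no	no	no
Crataegus azarolus	yes	no	absent
Sorbus aria	yes	no	no
Sorbus aucuparia	no	no	no
Sorbus domestica	no	no	absent
Sorbus torminalis	yes	yes	yes
Aesculus hippocastanus	yes	yes	no
Aesculus indica	yes	yes	absent
Fraxinus ornus	yes	no	yes
Fraxinus angustifolia	no	no	no
Fraxinus excelsior	no	no	no
Sambucus nigra	yes	no	yes
Sambucus ebulus	yes	no	no
Sambucus racemosa	yes	n.d.	yes
Passiflora incarnata	yes	no	yes
Passiflora edulis	yes	n.d.	yes
Punica granatum	yes	n.d.	yes
Ziziphus jujuba	yes	n.d.	yes
Ilex aquifolium	no	no	yes
Ilex latifolia	no	n.d.	no
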
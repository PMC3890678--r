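family	species	n_samples
Pinaceae	Cedrus atlantica	3
Pinaceae	Cedrus deodara	3
Pinaceae	Cedrus libani	3
Rosaceae	Crataegus monogyna	3
Rosaceae	Crataegus oxyacantha	2
Rosaceae	Crataegus azarolus	4
Rosaceae	Sorbus aria	3
Rosaceae	Sorbus aucuparia	2
Rosaceae	Sorbus domestica	3
Rosaceae	Sorbus torminalis	3
Sapindaceae	Aesculus hippocastanus	3
Sapindaceae	Aesculus indica	3
Oleaceae	Fraxinus ornus	5
Oleaceae	Fraxinus angustifolia	3
Oleaceae	Fraxinus excelsior	2
Adoxaceae	Sambucus nigra	5
Adoxaceae	Sambucus ebulus	2
Adoxaceae	Sambucus racemosa	1
Passifloraceae	Passiflora incarnata	2
Passifloraceae	Passiflora edulis	1
Lythraceae	Punica granatum	4
Rhamnaceae	Ziziphus jujuba	3
Aquifoliaceae	Ilex aquifolium	4
Aquifoliaceae	Ilex latifolia	1
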
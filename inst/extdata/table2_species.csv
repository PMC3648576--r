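scientific_name,common_name,threat_status,global_population,n_subpops,sr,t_percent
Copsychus sechellarum,Seychelles Magpie-robin,EN,178,2,114,64.0
Spheniscus demersus,African Penguin,EN,52000,6,26040,50.1
Zosterops modestus,Seychelles White-eye,EN,450,3,178,39.6
Sephanoides fernandensis,Juan Fernandez Firecrown,CR,3000,1,1137,37.9
Malaconotus alius,Uluguru Bush-shrike,CR,2400,1,881,36.7
Mimus trifasciatus,Floreana Mockingbird,CR,100,1,28,28.0
Camarhynchus pauper,Medium Tree-finch,CR,1660,1,460,27.7
Phoebastria irrorata,Waved Albatross,CR,34700,1,9612,27.7
Mimus melanotis,San Cristobal Mockingbird,EN,8000,1,2216,27.7
Camarhynchus heliobates,Mangrove Finch,CR,160,2,44,27.5
Spheniscus mendiculus,Galapagos Penguin,EN,1800,1,474,26.3
Artisornis moreaui,Long-billed Tailorbird,CR,250,1,55,22.0
Buteo ridgwayi,Ridgway's Hawk,CR,240,1,38,15.8
Polioptila clementsi,Iquitos Gnatcatcher,CR,250,1,39,15.6
Laterallus tuerosi,Junin Rail,EN,2500,1,388,15.5
Podiceps taczanowskii,Junin Grebe,CR,304,1,47,15.5
Hylonympha macrocerca,Scissor-tailed Hummingbird,EN,20000,1,2480,12.4
Pterodroma phaeopygia,Galapagos Petrel,CR,10000,4,1219,12.2
Terpsiphone corvina,Seychelles Paradise-flycatcher,CR,278,2,30,10.8
Zosterops albogularis,White-chested White-eye,CR,50,1,5,10.0
Grus americana,Whooping Crane,EN,382,1,36,9.4
Manorina melanotis,Black-eared Miner,EN,1000,1,94,9.4
Papasula abbotti,Abbott's Booby,EN,6000,1,564,9.4
Zosterops tenuirostris,Slender-billed White-eye,EN,2000,1,188,9.4
Ara ambiguus,Great Green Macaw,EN,3700,3,334,9.0
Pardalotus quadragintus,Forty-spotted Pardalote,EN,3800,2,339,8.9
Cacatua haematuropygia,Philippine Cockatoo,CR,2700,2,239,8.9
Aceros narcondami,Narcondam Hornbill,EN,340,1,27,7.9
Threskiornis bernieri,Madagascar Sacred Ibis,EN,3250,1,254,7.8
Myiotheretes pernix,Santa Marta Bush-tyrant,EN,2500,1,190,7.6
Anas laysanensis,Laysan Duck,CR,1100,2,82,7.5
Acrocephalus familiaris,Millerbird,CR,1000,1,74,7.4
Myadestes palmeri,Puaiohi,CR,500,1,37,7.4
Oreomystis bairdi,Akikiki,CR,1840,1,136,7.4
Crax blumenbachii,Red-billed Curassow,EN,250,3,16,6.4
Aratinga brevipes,Socorro Parakeet,EN,300,1,18,6.0
Mimus graysoni,Socorro Mockingbird,CR,420,1,25,6.0
Anas wyvilliana,Hawaiian Duck,EN,2525,1,148,5.9
Leptoptilos dubius,Greater Adjutant,EN,1000,2,52,5.2
Petroica traversi,Black Robin,EN,250,2,13,5.2
Phoebastria nigripes,Black-footed Albatross,EN,130000,3,6700,5.2
Strigops habroptila,Kakapo,CR,124,2,6,4.8
Pterodroma axillaris,Chatham Petrel,EN,1100,1,53,4.8
Pterodroma magentae,Magenta Petrel,CR,150,2,7,4.7
Psephotus chrysopterygius,Golden-shouldered Parrot,EN,2000,2,87,4.4
Eudyptes sclateri,Erect-crested Penguin,EN,170000,2,7392,4.3
Anas nesiotis,Campbell Islands Teal,CR,250,3,10,4.0
Fregata andrewsi,Christmas Frigatebird,CR,4800,1,188,3.9
Heteroglaux blewitti,Forest Owlet,CR,250,1,8,3.2
Pyrrhura griseipectus,Grey-breasted Parakeet,CR,250,1,8,3.2
Odontophorus strophium,Gorgeted Wood-quail,EN,4300,1,137,3.2
Porphyrio hochstetteri,Takahe,EN,220,2,7,3.2
Thinornis novaeseelandiae,Shore Plover,EN,220,1,6,2.7
Cyanoramphus malherbi,Malherbe's Parakeet,CR,663,3,18,2.7
Rollandia microptera,Titicaca Grebe,EN,3000,2,81,2.7
Phoebetria fusca,Sooty Albatross,EN,42000,1,1133,2.7
Carpodectes antoniae,Yellow-billed Cotinga,EN,794,1,20,2.5
Mergus octosetaceus,Brazilian Merganser,CR,250,1,6,2.4
Penelope albipennis,White-winged Guan,CR,250,3,6,2.4
Megadyptes antipodes,Yellow-eyed Penguin,EN,4800,3,110,2.3
Geothlypis beldingi,Belding's Yellowthroat,CR,1500,1,30,2.0
Torreornis inexpectata,Cuban Sparrow,EN,700,1,13,1.9
Conothraupis mesoleuca,Cone-billed Tanager,CR,250,1,4,1.6
Callaeas cinereus,Kokako,EN,1538,1,24,1.6
Pipile jacutinga,Black-fronted Piping-guan,EN,10000,1,156,1.6
Ardea humbloti,Madagascar Heron,EN,1500,1,22,1.5
Ardeola idae,Madagascar Pond-heron,EN,6000,1,85,1.4
Amazona vinacea,Vinaceous Amazon,EN,2500,3,30,1.2
Penelope perspicax,Cauca Guan,EN,1235,2,14,1.1
Apteryx mantelli,Northern Brown Kiwi,EN,25000,3,202,0.8
Amazona rhodocorytha,Red-browed Amazon,EN,2500,1,19,0.8
Eleothreptus candicans,White-winged Nightjar,EN,2400,1,18,0.8
Pedionomus torquatus,Plains-wanderer,EN,8000,2,50,0.6
Phytotoma raimondii,Peruvian Plantcutter,EN,1000,1,6,0.6
Curaeus forbesi,Forbes's Blackbird,EN,2500,1,12,0.5
Haliaeetus vociferoides,Madagascar Fish-eagle,CR,250,1,1,0.4
Eutriorchis astur,Madagascar Serpent-eagle,EN,250,1,1,0.4
Cistothorus apolinari,Apolinar's Wren,EN,1300,1,4,0.3
Anodorhynchus hyacinthinus,Hyacinth Macaw,EN,6500,1,18,0.3
Brotogeris pyrrhoptera,Grey-cheeked Parakeet,EN,15000,2,22,0.1
Anas bernieri,Madagascar Teal,EN,2500,1,2,0.1
Terenura sharpei,Yellow-rumped Antwren,EN,10000,1,8,0.1
Ara rubrogenys,Red-fronted Macaw,EN,4000,1,1,0.0
Diomedea sanfordi,Northern Royal Albatross,EN,17000,1,2,0.0
Thalassarche melanophrys,Black-browed Albatross,EN,1220000,2,77,0.0
Eleoscytalopus psychopompus,Bahia Tapaculo,CR,250,1,0,0.0
Zosterops chloronothus,Mauritius Olive White-eye,CR,296,1,0,0.0
Foudia rubra,Mauritius Fody,EN,328,1,0,0.0
Nesoenas mayeri,Pink Pigeon,EN,395,1,0,0.0
Psittacula eques,Mauritius Parakeet,EN,300,1,0,0.0
Trichocichla rufa,Long-legged Thicketbird,EN,250,3,0,0.0
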
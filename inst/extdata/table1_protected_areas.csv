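reserve_name,country,n_species,n_sole
Galapagos National Park,Ecuador,8,4
Pedra Talhada Biological Reserve,Brazil,6,0
Gough Island Nature Reserve,Saint Helena,6,1
Munchique National Natural Park,Colombia,5,0
South East Island (Rangatira) Nature Reserve,New Zealand,5,1
Emas National Park,Brazil,4,0
Frei Caneca Private Reserve,Brazil,4,0
Sooretama Biological Reserve,Brazil,4,0
Sierra Nevada de Santa Marta Biosphere Reserve,Colombia,4,1
French Southern and Antarctic Lands,France,4,0
Black River Gorges National Park,Mauritius,4,0
Fiordland National Park,New Zealand,4,0
Mangere Island Nature Reserve,New Zealand,4,0
Mt Canlaon Natural Park,Philippines,4,0
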
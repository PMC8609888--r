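(Cnidaria,(Xenacoelomorpha,((((Priapulida,Loricifera)Scalidophora,(Nematoda,(Tardigrada,(Onychophora,Arthropoda))Panarthropoda))Ecdysozoa,((Rotifera,Micrognathozoa)Gnathifera,((Gastrotricha,Platyhelminthes)Rouphozoa,((Bryozoa,Cycliophora)Polyzoa,(Annelida,(Mollusca,(Nemertea,(Brachiopoda,Phoronida))))Trochozoa)Lophotrochozoa)Platytrochozoa)Spiralia)Protostomia,((Tunicata,Craniata)Chordata,Echinodermata)Deuterostomia)Nephrozoa)Bilateria)Planulozoa;
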
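id	chrom	pos	category	population	note
Sma-USC277	C05	16721340	High-GD	Broodstock	Resistance and survival time to Philasterides dicentrarchi; resistance to Aeromonas salmonicida
4559_39	C06	1109461	High-GD	Broodstock	Genetic divergence between farm (ORI1) and wild turbot
11910	C08	833346	High-GD	Broodstock	Balancing selection; global outlier
Sma-E99	C08	1047506	High-GD	Broodstock	Divergent selection
Sma-USC266	C09	23265541	High-GD	Broodstock	Growth
Sma-USC223	C02	18889875	Low-GD	Broodstock	Growth (body weight and body length)
Sma-USC50	C02	19267847	Low-GD	Broodstock	Growth (body weight and body length)
Sma-E183	C02	19293723	Low-GD	Broodstock	Growth (body weight)
7415_42	C02	18430391	Low-GD	Broodstock	Balancing selection; divergence Baltic Sea and Black Sea vs Atlantic turbot
Sma-USC88	C12	16323329	Low-GD	Broodstock	Survival time to VHSV
SmaSNP_298	C19	13228742	Low-GD	Broodstock	Divergent selection
12273_75	C22	8140606	Low-GD	Broodstock	Genetic divergence between farm (ORI1) and wild turbot
1412_35	C01	25668281	High-GD	Wild	Genetic divergence between farm (ORI2) and wild turbot
Sma-E99	C08	1047506	High-GD	Wild	Divergent selection
SmaUSC-E23	C08	9946986	High-GD	Wild	Resistance and survival time to Philasterides dicentrarchi; resistance to Aeromonas salmonicida
FAR2	C10	23144173	High-GD	Wild	Positional gene marker; growth QTL
13637_50	C05	27533562	Low-GD	Wild	Genetic divergence between farm (ORI1) and wild turbot
PKM	C05	19976976	Low-GD	Wild	Positional gene marker; growth QTL
Sma-USC16	C19	9911085	Low-GD	Wild	Growth (body weight, body length and condition factor)
Sma-USC38	C20	10007284	Low-GD	Wild	Stabilizing selection; resistance and survival time to Philasterides dicentrarchi
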
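suborder	family	species	accession	size_bp
Charadrii	Haematopodidae	Haematopus ater	AY074886	16791
Charadrii	Recurvirostridae	Recurvirostra avosetta	KP757766	16897
Charadrii	Charadriidae	Vanellus cinereus	KM404175	17074
Charadrii	Charadriidae	Vanellus cinereus	KM873665	17135
Charadrii	Charadriidae	Vanellus vanellus	KM577158	16795
Scolopaci	Jacanidae	Jacana jacana	KJ631049	16975
Scolopaci	Jacanidae	Jacana spinosa	KJ631048	17079
Scolopaci	Scolopacidae	Scolopax rusticola	KM434134	16984
Scolopaci	Scolopacidae	Arenaria interpres	AY074885	16725
Scolopaci	Scolopacidae	Eurynorhynchus pygmeus	KP742478	16707
Scolopaci	Scolopacidae	Gallinago stenura	KY056596	16899
Lari	Laridae	Chroicocephalus brunnicephalus	JX155863	16769
Lari	Laridae	Chroicocephalus ridibundus	KM577662	16807
Lari	Laridae	Chroicocephalus saundersi	JQ071443	16725
Lari	Laridae	Larus crassirostris	KM507782	16746
Lari	Laridae	Larus dominicanus	AY293619	16701
Lari	Laridae	Ichthyaetus relictus	KC760146	16586
Lari	Laridae	Sternula albifrons	KT350612	16357
Lari	Stercorariidae	Stercorarius maccormicki	KM401546	16669
Lari	Alcidae	Synthliboramphus antiquus	AP009042	16730
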
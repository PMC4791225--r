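gene	log2fc	p	fdr
G00001	-0.0268024425533702	0.12954331742605657	0.5685232700780034
G00002	-0.0184397290746153	0.2511794459360728	0.8635859278962017
G00003	0.014861934751471122	0.653811670958643	0.6741732146590949
G00004	0.11884900910009895	0.30801775172516144	0.7559150511398911
G00005	0.004393101006940326	0.12176595727929354	0.5449261726811528
G00006	0.9762362973699326	0.0029772789744637474	0.004418325643055141
G00007	-1.2796402810437515	4.6817495107016904e-4	0.0015636801975779237
G00008	-0.023925341212012452	0.19845819692906497	0.24719073195010424
G00009	-1.5999707732412243	8.339978072902893e-5	9.411336155608296e-5
G00010	0.05019672109873217	0.17416572231920097	0.24922708421945572
G00011	-0.01972768432202164	0.2127732423567681	0.4420466117560864
G00012	0.004231655138925742	0.191355622257896	0.34965257272124295
G00013	-0.026259233071811213	0.3124071349796958	0.6263102432712913
G00014	0.0991081538451738	0.44038104734980654	0.7454316210001708
G00015	-1.2167527265457632	0.00403546053552812	0.006851162121165544
G00016	-0.028368473717658972	0.4641579565508702	0.8911468386650085
G00017	-0.021663288319305155	0.13414633064312798	0.3634621059522033
G00018	0.01108747188129989	0.4228829906282262	0.5054059382528067
G00019	0.007185992872122672	0.16523247351158482	0.36018848549574617
G00020	0.06257709943910608	0.43318923146615745	0.9094468249008061
G00021	-0.07311705530904572	0.3929885527817578	0.9084405580535531
G00022	-0.001204561773831287	0.08615291084937649	0.3954776503145695
G00023	2.108068869040553	0.0015006822176208024	0.0028520957357250154
G00024	0.02232009838288826	0.3673523170476528	0.72757006008178
G00025	-0.042078150349609884	0.13834199488940735	0.34942701142281296
G00026	0.07283407296178578	0.2646850295945549	0.6049849100410938
G00027	0.134993218410239	0.48788859218040964	0.48881752472370865
G00028	0.002649933206300763	0.5496413606427969	0.9062744924798609
G00029	0.016039124247466334	0.2759027796540319	0.4277154978364706
G00030	0.00933589252694044	0.44528422353914215	0.9449137212708594
G00031	0.026354994065485034	0.5652373254118318	0.8956139007583261
G00032	-0.009692650484359548	0.17404454345871387	0.27667604777961974
G00033	-0.0028297363614361902	0.43431359427790345	0.8077267121523619
G00034	-0.031375259185974176	0.14225276558446148	0.22121530938893558
G00035	-0.015487886793167212	0.18525095546097622	0.49363972526043653
G00036	0.0013441700843982423	0.12878620750148265	0.26568787805736066
G00037	0.042598726347845256	0.30593910202516933	0.7255543833598495
G00038	0.057451251910073935	0.19452227092346125	0.6861325616016984
G00039	0.02709076900801914	0.2207415127067176	0.4410752918571234
G00040	0.013894772138795556	0.5302452791553467	0.7465103002265097
G00041	-0.00792849794155025	0.30748351761235726	0.6368972025811672
G00042	0.8882938567125969	0.0046486243336633605	0.006855514561757445
G00043	-0.037873477192720065	0.1017022763442797	0.3143411431461573
G00044	0.08103151817173115	0.42160315935400894	0.5142774928361178
G00045	-0.04671087672023165	0.15663203135243167	0.4278359722346068
G00046	0.008127187167458168	0.4313651043721007	0.5458325890824198
G00047	-0.8477958467490011	0.0047447611492741236	0.007921520026866347
G00048	-0.09160301051070308	0.29132169362203286	0.7452903548255563
G00049	0.02178059265111469	0.2153720487602664	0.3516889959573746
G00050	-0.036149959048604484	0.539666531748087	0.7976046847179532
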
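0.546113003557548,0.504786735214293,0.932255441369489,0.94476381810382,0.666278046602383,0.328115471452475,0.71052990113385,0.511731976224109,0.292092248145491,0.998885071650147,0.269555038120598,1.19399910634384,1.15829376205802,0.522705295169726,1.13870539264753,0.239990456542,1.07635916960426,0.55893292655237,0.515550103317946,0.822241740813479,0.407275721943006
0.412971417000517,0.743664464494213,0.802364798076451,0.386374698532745,1.05694967932068,0.75622059199959,0.209299010504037,0.788979009073228,0.42137945657596,0.598552096448839,1.05995057900436,1.15656519941986,0.285818365681916,1.13669561645947,0.869851216720417,1.16166342054494,0.392095987033099,0.494052116340026,0.766143390955403,0.244645869871601,0.347385060088709
0.959576294803992,1.16339347586036,0.398595024412498,0.774629416689277,1.0613712200895,0.806799182947725,0.360531563218683,1.12932071350515,0.791637168312445,0.218999152584001,0.986039771744981,0.87895610560663,0.295107700210065,0.573134893598035,1.16040123561397,0.437390307011083,0.308331904280931,0.485927533637732,1.07907111714594,0.385630297055468,1.06491137905978
0.971213851869106,0.221919067949057,0.327152944914997,0.73116774186492,0.809960932983085,0.243122604023665,1.0402283298783,1.09154687267728,0.982814162783325,0.868335079681128,0.910312667069957,1.03190064947121,0.542288506217301,0.992367016896605,0.730919462908059,0.586197158601135,0.420608786679804,0.33851358811371,0.313708988530561,0.726258570607752,0.200367855187505
0.686781484214589,0.856473632436246,0.920691591035575,0.717738241003826,0.303844980243593,0.655159580335021,0.686542405327782,0.448642920283601,1.01411541788839,1.11368722799234,1.0397682113573,0.38132939003408,0.720642063813284,1.16397862653248,0.570594993932173,0.598681093007326,0.865059553226456,0.726060844538733,0.489234577212483,0.568572713108733,1.13940001865849
0.352513497741893,1.16634671953507,1.03636741060764,0.290654052561149,0.350209616636857,0.363195228902623,0.543373247887939,0.93306534695439,1.06131144920364,0.624459769623354,0.716296454938129,0.561289626453072,1.05078836069442,1.03006192930043,1.18723673098721,0.474705516407266,0.902674779109657,0.327053328789771,1.03319002925418,0.821191172627732,1.19558547604829
1.05712857893668,1.1361676608678,1.14023278634995,0.227603789698333,0.916524460120127,0.327915382385254,0.771318336296827,0.775033477507532,1.07844078615308,0.801295428583398,0.346746784681454,0.374493033904582,0.522233771206811,0.656781074171886,0.479886475764215,0.93706889222376,0.593677730113268,0.567730327183381,1.1556724105496,0.865597778977826,0.890179688390344
0.261185099650174,1.1016299105715,1.14868314475752,0.278699151985347,1.15523152523674,1.01497254408896,0.974176279082894,0.638770586391911,0.255933716474101,0.325195608474314,0.318054124061018,0.433434630092233,0.949945637304336,0.573101418837905,0.663397484272718,1.02675417535938,0.862727404851466,0.459885121602565,0.547814964130521,0.998777665942907,0.825445960555226
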
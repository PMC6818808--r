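theta,re,im,val
1.8112136764782445,9.782599668511555,-5.586413217207969,4.8804650860585296058e-30
-1.611732997048973,2.2658449713595283,0.1626061180412255,0.00092635411018995190494
-5.550052098696181,1.8341678507637336,0.027276765525783064,-0.0055246039163620889272
-4.91144383987362,13.066005941505336,-6.882313222806097,4.9805268829049992952e-56
-4.5143764662042525,12.793123755361167,5.229633994752609,1.1786543730339921159e-61
5.372507309484067,6.7748450417497335,1.7266806699373962,-1.009163433942735202e-20
5.71506126711504,17.35537816366321,-1.6531124055875175,-2.6792042789964344658e-132
-2.524688564019885,1.4928221504709127,1.0702593118260884,-0.0045729203405908030101
-2.2982181107767876,4.413226992387382,-3.3735392232250296,-4.8714190068131598871e-6
0.9792019639495955,24.50217813768894,-5.108377921217,-1.6976315656742655908e-252
0.5729335885146938,19.203512720892903,-2.0416393163883004,6.8879049951357203003e-161
-3.5284954461680815,1.9773903517023619,-1.7416807948195598,0.067084943303751444757
-2.230233955478502,20.4439591981354,-1.158523109289554,-3.0093437666882149385e-183
-2.4027960376358117,17.6082997188784,-0.7490499780675943,1.1152724945258349784e-136
-3.0708418713341654,23.851946497522487,3.18391093967314,-4.5277011287680988705e-245
4.501649946881146,17.275268936734264,0.4031440609832231,-2.4238195020815928504e-133
5.762098169910985,21.91041415423261,-3.3929957617570157,5.04802625202021735e-206
3.0856911547829924,3.6301667698233673,-0.5944556231243481,-3.8195814387659257196e-7
-5.5295129154307485,4.644337586349092,-0.10251817459394896,-5.0866207496472916434e-11
0.876311283328608,20.079654110378417,4.23313385940501,-4.0576048623672625053e-170
2.343544395283912,26.276786573743557,-2.9800397944304517,-1.9030965879692612882e-298
-0.5255360243830438,17.871659325440053,1.278323268519875,2.3195719742735299171e-140
-0.31081995096426596,25.21503663732499,7.1148975217269985,1.4828297955383791688e-256
2.4179042556530863,19.958150943692768,-7.0292891584444845,-4.3843933302236097961e-154
3.8630974393165793,19.449152750377298,7.889535031466146,1.4718106225874117227e-139
2.023832590610258,8.609406409615062,-1.827336920852627,-8.7968089391082912984e-33
-3.9834194531214653,0.7746315488620983,-0.05934407940466324,-0.17811057774331676564
3.218795861670248,3.601164255003784,-3.176555159862946,-0.0065543264364579409392
-1.3086035624012755,3.9672726383586583,-2.002561529203663,-6.3227119937434527386e-7
-0.609751188608028,26.15551702637635,-6.710699180797782,5.4538825611452642924e-280
3.8313580540288967,16.52825328340672,6.1341412230642,-1.5700311753869178928e-104
-1.0164417934596166,25.933135643985604,-3.5452629677776457,-3.6879221581273733677e-289
5.492774447567895,10.82725784341558,6.147085235171472,8.876905240633072829e-37
-3.216517598165571,4.612535083154157,-2.986914173283023,1.0224207630491326265e-7
1.0694820447870672,7.076748902057747,-0.212829963093502,1.2120224356161280442e-23
-0.9726419864960647,7.956123917026283,-7.890985485428829,0.0052262469790145827759
5.437175106301144,11.140681829552287,1.0614595793022712,-1.0002981189855387616e-55
1.4111129929095316,20.74576034836574,0.2478629291324541,1.8073194826341284705e-189
4.794396120695426,20.31838246524009,-7.136113708419357,3.2858185334346304154e-160
3.5744774543587923,23.421087772111576,5.992210946151625,4.2253303093865633103e-225
1.234,50.0,0.0,-1.9545727412430536204e-1088
1.234,50.0,5.0,8.9512453555082415722e-1078
1.234,50.0,-5.0,1.4377921659865022206e-1077
1.234,200.0,0.0,-4.4259026938495356837e-17375
1.234,200.0,5.0,2.2712442334189429074e-17364
1.234,200.0,-5.0,2.1748156744227125744e-17365
1.234,900.0,0.0,-1.7447331156738131105e-351782
1.234,900.0,5.0,1.2632327884468512246e-351771
1.234,900.0,-5.0,7.2566360146363603134e-351772
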
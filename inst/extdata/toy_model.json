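{"keys":["aa:N-N","aa:I-N","aa:L-N","aa:N-V","aa:I-V","ad:A-I","ad:I-H","ad:L-M","dd:H-M","dad:H-R-M","dad:I-T-M","aa:T-V","dd:I-L","ad:L-L","ge:K-K","aa:I-I","ge:K-Q","ad:A-M","dd:L-L","dad:V-V-H","aa:A-T","dd:I-I","dad:L-T-V","dd:H-I","dad:V-V-I","ad:V-M","dad:L-V-L","ge:E-E","dad:I-K-M","ad:R-I","ad:T-L","dd:L-M","ge:E-Q","ge:L-L"],"weights":[-0.80000000000000004,1.2,1.2,1.2,0.40564846100288232,0.21079153060246814,-0.51626965893636456,-0.60304466174849969,0.78004958699096605,-0.37952073354669769,-0.17138454779843698,0.55529004004421889,0.44235167533277703,-0.75858976882037243,-0.45004192376349555,-0.31254424009493897,0.27268095899151346,-0.55183799147256285,-0.15651334765097172,1.121068690730959,0.9460657211877318,-0.79692416540970878,-0.51158779117650321,-0.52861741688119734,0.46562184952537178,-0.1044150546330478,0.35439680197940543,0.2775072898600387,-0.0041361840401447905,-0.047350325175619268,0.048608581994157872,0.17268234586685716,-0.7295700014288875,-0.27026800806840368],"C1":1,"C2":1,"epsilon":0.10000000000000001,"E_cutoff":3.6989700043360187,"intercept":4.8407419310522686,"categories":["aa","dd","ge","eg","ad","da","de","ga","ada","dad","gde","gae","edg","eag","agd","aed","dea","dga"],"roles":"both"}
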
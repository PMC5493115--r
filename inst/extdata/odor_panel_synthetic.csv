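"odor_id","name","valence","solvent","dilution"
"O01","synthetic_odor_O01","attractive","mineral_oil",0.001
"O02","synthetic_odor_O02","attractive","mineral_oil",0.001
"O03","synthetic_odor_O03","attractive","mineral_oil",0.001
"O04","synthetic_odor_O04","attractive","mineral_oil",0.001
"O05","synthetic_odor_O05","attractive","mineral_oil",0.001
"O06","synthetic_odor_O06","attractive","water",0.001
"O07","synthetic_odor_O07","attractive","mineral_oil",0.001
"O08","synthetic_odor_O08","attractive","mineral_oil",0.001
"O09","synthetic_odor_O09","aversive","mineral_oil",0.001
"O10","synthetic_odor_O10","aversive","mineral_oil",0.001
"O11","synthetic_odor_O11","aversive","mineral_oil",0.001
"O12","synthetic_odor_O12","aversive","mineral_oil",0.001
"O13","synthetic_odor_O13","aversive","mineral_oil",0.001
"O14","synthetic_odor_O14","aversive","mineral_oil",0.001
"O15","synthetic_odor_O15","aversive","water",0.001
"O16","synthetic_odor_O16","aversive","mineral_oil",0.001
"O17","synthetic_odor_O17","aversive","mineral_oil",0.001
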
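player_id,mu,sigma
p1,21.0314110612,2.7531769550
p2,21.8709574149,3.2187166530
p3,21.6889655178,2.6283185450
p4,24.8140973358,2.2530052635
p5,32.4353704973,3.0738603015
p6,33.2052287034,3.3393963173
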
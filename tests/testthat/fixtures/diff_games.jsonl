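{"game_id": "g0", "seq": 0, "teams": [["p1", "p5"], ["p2", "p4"]], "outcome": [1, 0]}
{"game_id": "g1", "seq": 1, "teams": [["p6"], ["p1"]], "outcome": [0, 1]}
{"game_id": "g2", "seq": 2, "teams": [["p2"], ["p4"]], "outcome": [1, 0]}
{"game_id": "g3", "seq": 3, "teams": [["p6"], ["p2"]], "outcome": [0, 1]}
{"game_id": "g4", "seq": 4, "teams": [["p5", "p3"], ["p1", "p2"]], "outcome": [0, 1]}
{"game_id": "g5", "seq": 5, "teams": [["p2"], ["p1"]], "outcome": [1, 0]}
{"game_id": "g6", "seq": 6, "teams": [["p4"], ["p6"]], "outcome": [1, 0]}
{"game_id": "g7", "seq": 7, "teams": [["p5"], ["p2"]], "outcome": [0, 1]}
{"game_id": "g8", "seq": 8, "teams": [["p6", "p3"], ["p5", "p1"]], "outcome": [0, 1]}
{"game_id": "g9", "seq": 9, "teams": [["p2"], ["p3"]], "outcome": [0, 1]}
{"game_id": "g10", "seq": 10, "teams": [["p4", "p6"], ["p1", "p5"]], "outcome": [1, 0]}
{"game_id": "g11", "seq": 11, "teams": [["p2"], ["p6"]], "outcome": [1, 0]}
{"game_id": "g12", "seq": 12, "teams": [["p3", "p5"], ["p1", "p2"]], "outcome": [0, 1]}
{"game_id": "g13", "seq": 13, "teams": [["p3"], ["p1"]], "outcome": [0, 1]}
{"game_id": "g14", "seq": 14, "teams": [["p3", "p5"], ["p1", "p4"]], "outcome": [1, 0]}
{"game_id": "g15", "seq": 15, "teams": [["p3", "p5"], ["p2", "p4"]], "outcome": [1, 0]}
{"game_id": "g16", "seq": 16, "teams": [["p4"], ["p1"]], "outcome": [0, 1]}
{"game_id": "g17", "seq": 17, "teams": [["p2", "p6"], ["p4", "p1"]], "outcome": [1, 0]}
{"game_id": "g18", "seq": 18, "teams": [["p1"], ["p5"]], "outcome": [1, 0]}
{"game_id": "g19", "seq": 19, "teams": [["p1"], ["p4"]], "outcome": [1, 0]}
{"game_id": "g20", "seq": 20, "teams": [["p3"], ["p5"]], "outcome": [1, 0]}
{"game_id": "g21", "seq": 21, "teams": [["p4"], ["p5"]], "outcome": [1, 0]}
{"game_id": "g22", "seq": 22, "teams": [["p3"], ["p4"]], "outcome": [0, 1]}
{"game_id": "g23", "seq": 23, "teams": [["p6", "p4"], ["p3", "p5"]], "outcome": [1, 0]}
{"game_id": "g24", "seq": 24, "teams": [["p4"], ["p1"]], "outcome": [0, 1]}
{"game_id": "g25", "seq": 25, "teams": [["p4"], ["p1"]], "outcome": [0, 1]}
{"game_id": "g26", "seq": 26, "teams": [["p1", "p3"], ["p5", "p2"]], "outcome": [1, 0]}
{"game_id": "g27", "seq": 27, "teams": [["p5", "p2"], ["p1", "p3"]], "outcome": [0, 1]}
{"game_id": "g28", "seq": 28, "teams": [["p4"], ["p6"]], "outcome": [1, 0]}
{"game_id": "g29", "seq": 29, "teams": [["p6", "p3"], ["p5", "p4"]], "outcome": [0, 1]}
{"game_id": "g30", "seq": 30, "teams": [["p4"], ["p3"]], "outcome": [0, 1]}
{"game_id": "g31", "seq": 31, "teams": [["p6"], ["p4"]], "outcome": [0, 1]}
{"game_id": "g32", "seq": 32, "teams": [["p5"], ["p2"]], "outcome": [0, 1]}
{"game_id": "g33", "seq": 33, "teams": [["p2", "p4"], ["p6", "p5"]], "outcome": [1, 0]}
{"game_id": "g34", "seq": 34, "teams": [["p1", "p4"], ["p3", "p5"]], "outcome": [1, 0]}
{"game_id": "g35", "seq": 35, "teams": [["p3"], ["p2"]], "outcome": [1, 0]}
{"game_id": "g36", "seq": 36, "teams": [["p4"], ["p6"]], "outcome": [1, 0]}
{"game_id": "g37", "seq": 37, "teams": [["p4"], ["p1"]], "outcome": [1, 0]}
{"game_id": "g38", "seq": 38, "teams": [["p5", "p4"], ["p1", "p3"]], "outcome": [0, 1]}
{"game_id": "g39", "seq": 39, "teams": [["p4"], ["p3"]], "outcome": [0, 1]}
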
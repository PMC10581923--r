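tank_id,diet_id,n_fish,initial_weight,final_weight,feed_intake,duration
T01,D1,14,83.8,247.9,135.5,38
T02,D1,14,83.8,247.9,135.5,38
T03,D1,14,83.8,247.9,135.5,38
T04,D2,14,83.7,274.4,149,38
T05,D2,14,83.7,274.4,149,38
T06,D2,14,83.7,274.4,149,38
T07,D3,14,83.8,271.6,145,38
T08,D3,14,83.8,271.6,145,38
T09,D3,14,83.8,271.6,145,38
T10,D4,14,84.3,282,152.8,38
T11,D4,14,84.3,282,152.8,38
T12,D4,14,84.3,282,152.8,38
T13,D5,14,83.8,267.7,140.5,38
T14,D5,14,83.8,267.7,140.5,38
T15,D5,14,83.8,267.7,140.5,38
T16,D6,14,84.3,284.4,151.7,38
T17,D6,14,84.3,284.4,151.7,38
T18,D6,14,84.3,284.4,151.7,38
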
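{"objective":"Healing environment in street spaces of a high-density city","evaluation_set":["Poor","Relatively Poor","General","Good","Very Good"],"criteria":[{"id":"u1","label":"Positive things to distracting attention","weight":0.35,"leaves":[{"id":"u11","label":"Plants","weight":0.06},{"id":"u12","label":"Social interaction","weight":0.06},{"id":"u13","label":"Shopping behavior","weight":0.39},{"id":"u14","label":"Spatial interest","weight":0.12},{"id":"u15","label":"Pedestrians or events in the street","weight":0.38}]},{"id":"u2","label":"Social/spatial support","weight":0.12,"leaves":[{"id":"u21","label":"Street railing","weight":0.11},{"id":"u22","label":"Building wall","weight":0.23},{"id":"u23","label":"Street corner","weight":0.09},{"id":"u24","label":"Public health facilities","weight":0.07},{"id":"u25","label":"Shade and rain shelter","weight":0.09},{"id":"u26","label":"Pillar (electric pole","weight":0.3},{"id":"u27","label":"Children","weight":0.12}]},{"id":"u3","label":"Controllability","weight":0.07,"leaves":[{"id":"u31","label":"Lighting","weight":0.16},{"id":"u32","label":"Visual accessibility","weight":0.25},{"id":"u33","label":"Street space navigation system","weight":0.49},{"id":"u34","label":"Spatial selections (safe","weight":0.1}]},{"id":"u4","label":"Eliminating environmental stress factors","weight":0.12,"leaves":[{"id":"u41","label":"Physical comfort","weight":0.47},{"id":"u42","label":"Psychological comfort","weight":0.47},{"id":"u43","label":"Spatial occupancy of car and motorcycle","weight":0.05}]},{"id":"u5","label":"Stimulating positive feeling","weight":0.35,"leaves":[{"id":"u51","label":"Microclimate environment","weight":0.49},{"id":"u52","label":"Opportunity of rest and relax","weight":0.3},{"id":"u53","label":"Perception of physical and mental health","weight":0.21}]}]}
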
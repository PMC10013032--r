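{
  "description": "Pre-registered manual trace of the acute pain-reflex scenario: FOP net with m=n=p=1, a single stimulus staged at tick 0 with strength 5.0 against an initial receptor threshold of 3.0, processing and effector delays of 1 tick. Scheduling convention: synchronous ticks; per-tick transition firing order En0, En1, I1, S, S1, O1, En2; a token moved or created during tick t is frozen until tick t+1. Derived by hand before the engine was implemented.",
  "scheduling": "synchronous; order En0, En1, I1..Im, S, S1..Sn, O1..Op, En2; move/create freezes a token for the rest of the tick",
  "path": [
    {"tick": 0, "transition": "En0", "event": "eps_star splits; child eps enters e1"},
    {"tick": 1, "transition": "En1", "event": "eps moves e1 -> i1_1 (routed to receptor 1)"},
    {"tick": 2, "transition": "I1",  "event": "strength 5.0 > threshold 3.0: eps moves i1_1 -> i1_2"},
    {"tick": 3, "transition": "S",   "event": "eps unites into omega in s (registration); omega splits sigma -> s1_1"},
    {"tick": 4, "transition": "S1",  "event": "sigma moves s1_1 -> s1_3; component processing starts"},
    {"tick": 5, "transition": "S1",  "event": "delay 1 elapsed: sigma splits sigma_prime -> s1_2"},
    {"tick": 6, "transition": "S",   "event": "sigma_prime unites into omega (component response); omega splits pi -> o1_1"},
    {"tick": 7, "transition": "O1",  "event": "pi moves o1_1 -> o1_3 and unites with phi; effector processing starts"},
    {"tick": 8, "transition": "O1",  "event": "delay 1 elapsed: phi splits phi_prime -> o1_2"},
    {"tick": 9, "transition": "En2", "event": "phi_prime enters e2 as zeta (total system reaction)"},
    {"tick": 10, "transition": "En0", "event": "zeta moves e2 -> e0 and unites with eps_star"}
  ],
  "zeta_emission_tick": 9,
  "response_latency": 9
}
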
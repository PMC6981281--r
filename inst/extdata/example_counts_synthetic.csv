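time_days,field_id,count
31,t31_f001,7
31,t31_f002,2
31,t31_f003,1
31,t31_f004,5
31,t31_f005,6
31,t31_f006,1
31,t31_f007,6
31,t31_f008,8
31,t31_f009,3
31,t31_f010,5
31,t31_f011,7
31,t31_f012,2
31,t31_f013,2
31,t31_f014,4
31,t31_f015,8
31,t31_f016,8
31,t31_f017,3
31,t31_f018,4
31,t31_f019,3
31,t31_f020,1
31,t31_f021,7
31,t31_f022,3
31,t31_f023,4
31,t31_f024,3
31,t31_f025,4
31,t31_f026,2
31,t31_f027,6
31,t31_f028,6
31,t31_f029,2
31,t31_f030,3
92,t92_f001,1
92,t92_f002,2
92,t92_f003,3
92,t92_f004,1
92,t92_f005,3
92,t92_f006,2
92,t92_f007,2
92,t92_f008,2
92,t92_f009,4
92,t92_f010,2
92,t92_f011,2
92,t92_f012,3
92,t92_f013,2
92,t92_f014,0
92,t92_f015,3
92,t92_f016,1
92,t92_f017,3
92,t92_f018,1
92,t92_f019,1
92,t92_f020,3
92,t92_f021,5
92,t92_f022,4
92,t92_f023,3
92,t92_f024,2
92,t92_f025,1
92,t92_f026,1
92,t92_f027,2
92,t92_f028,4
92,t92_f029,3
92,t92_f030,1
184,t184_f001,1
184,t184_f002,1
184,t184_f003,0
184,t184_f004,2
184,t184_f005,3
184,t184_f006,3
184,t184_f007,1
184,t184_f008,2
184,t184_f009,2
184,t184_f010,2
184,t184_f011,1
184,t184_f012,3
184,t184_f013,4
184,t184_f014,0
184,t184_f015,1
184,t184_f016,2
184,t184_f017,3
184,t184_f018,2
184,t184_f019,1
184,t184_f020,1
184,t184_f021,0
184,t184_f022,2
184,t184_f023,3
184,t184_f024,2
184,t184_f025,3
184,t184_f026,2
184,t184_f027,4
184,t184_f028,4
184,t184_f029,4
184,t184_f030,1
368,t368_f001,2
368,t368_f002,1
368,t368_f003,0
368,t368_f004,1
368,t368_f005,1
368,t368_f006,1
368,t368_f007,0
368,t368_f008,0
368,t368_f009,2
368,t368_f010,1
368,t368_f011,1
368,t368_f012,0
368,t368_f013,1
368,t368_f014,3
368,t368_f015,2
368,t368_f016,0
368,t368_f017,1
368,t368_f018,2
368,t368_f019,2
368,t368_f020,1
368,t368_f021,0
368,t368_f022,2
368,t368_f023,0
368,t368_f024,0
368,t368_f025,3
368,t368_f026,1
368,t368_f027,3
368,t368_f028,0
368,t368_f029,1
368,t368_f030,1
552,t552_f001,0
552,t552_f002,0
552,t552_f003,0
552,t552_f004,0
552,t552_f005,0
552,t552_f006,0
552,t552_f007,0
552,t552_f008,0
552,t552_f009,0
552,t552_f010,0
552,t552_f011,0
552,t552_f012,0
552,t552_f013,2
552,t552_f014,1
552,t552_f015,0
552,t552_f016,0
552,t552_f017,1
552,t552_f018,0
552,t552_f019,0
552,t552_f020,1
552,t552_f021,0
552,t552_f022,0
552,t552_f023,0
552,t552_f024,0
552,t552_f025,1
552,t552_f026,0
552,t552_f027,1
552,t552_f028,1
552,t552_f029,0
552,t552_f030,0
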
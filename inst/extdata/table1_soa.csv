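"Phase","Screening","Study period","Study period","Study period","Study period","Study period","Unscheduled"
"Visit ID","1","2","3","4","5","6","U"
"Visit timing","-Days 28 to 1","Day 1","Day 7","Day 14","Day 21","Day 28","As required"
"Activity","","","","","","",""
"Demographics","X","","","","","",""
"Medical history","X","","","","","",""
"Inclusion and exclusion criteria","X","","X","","","",""
"Vital signs","X","X","X","X","X","X","X"
"Procedure","X","X","","","","",""
"Concomitant medication","X","X","X","X","X","X","X"
"AE and SAE","X","X","X","X","X","X","X"
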
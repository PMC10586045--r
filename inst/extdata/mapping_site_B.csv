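"local_statement_id","catalog_statement_id"
"B_L001","PAT01"
"B_L002","PAT02"
"B_L003","PAT03"
"B_L004","PAT04"
"B_L005","PAT05"
"B_L006","PAT06"
"B_L007","PAT07"
"B_L008","PAT08"
"B_L009","PAT09"
"B_L010","PAT10"
"B_L011","THX01"
"B_L012","COG01"
"B_L013","COG02"
"B_L014","COG03"
"B_L015","COG04"
"B_L016","COG05"
"B_L017","RSK01"
"B_L018","COM01"
"B_L019","UNI01"
"B_L020","UNI02"
"B_L021","UNI03"
"B_L022","UNI04"
"B_L023","UNI05"
"B_L024","ENM01"
"B_L025","ENM02"
"B_L026","ENM03"
"B_L027","ENM04"
"B_L028","ENM05"
"B_L029","ENM06"
"B_L030","ENM07"
"B_L031","ENM08"
"B_L032","ENM09"
"B_L033","RTC01"
"B_L034","RTC02"
"B_L035","RTC03"
"B_L036","RTC04"
"B_L037","RTC05"
"B_L038","RTC06"
"B_L039","RTC07"
"B_L040","RTC08"
"B_L041","RTC09"
"B_L042","RTC10"
"B_L043","EDU01"
"B_L044","EDU02"
"B_L045","EDU03"
"B_L046","EDU04"
"B_L047","INF01"
"B_X001",""
"B_X002",""
"B_X003",""
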
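"local_statement_id","catalog_statement_id"
"A_L001","PAT01"
"A_L002","PAT02"
"A_L003","PAT03"
"A_L004","PAT04"
"A_L005","PAT05"
"A_L006","PAT06"
"A_L007","PAT07"
"A_L008","PAT08"
"A_L009","PAT09"
"A_L010","PAT10"
"A_L011","PAT11"
"A_L012","PAT12"
"A_L013","PAT13"
"A_L014","PAT14"
"A_L015","PAT15"
"A_L016","PAT16"
"A_L017","PAT17"
"A_L018","PAT18"
"A_L019","PAT19"
"A_L020","COG01"
"A_L021","COG02"
"A_L022","COG03"
"A_L023","COG04"
"A_L024","COM01"
"A_L025","SIT01"
"A_L026","UNI01"
"A_L027","UNI02"
"A_L028","UNI03"
"A_L029","UNI04"
"A_L030","UNI05"
"A_L031","UNI06"
"A_L032","UNI07"
"A_L033","UNI08"
"A_L034","UNI09"
"A_L035","UNI10"
"A_L036","ENM01"
"A_L037","ENM02"
"A_L038","ENM03"
"A_L039","RTC01"
"A_L040","RTC02"
"A_L041","RTC03"
"A_L042","RTC04"
"A_L043","RTC05"
"A_L044","RTC06"
"A_L045","RTC07"
"A_L046","EDU01"
"A_L047","EDU02"
"A_L048","EDU03"
"A_L049","EDU04"
"A_L050","EDU05"
"A_L051","EDU06"
"A_L052","INF01"
"A_X001",""
"A_X002",""
"A_X003",""
"A_L900","PAT01"
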
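"local_statement_id","catalog_statement_id"
"C_L001","PAT01"
"C_L002","PAT02"
"C_L003","PAT03"
"C_L004","PAT04"
"C_L005","PAT05"
"C_L006","PAT06"
"C_L007","PAT07"
"C_L008","PAT08"
"C_L009","PAT09"
"C_L010","PAT10"
"C_L011","PAT11"
"C_L012","PAT12"
"C_L013","PAT13"
"C_L014","PAT14"
"C_L015","PAT15"
"C_L016","PAT16"
"C_L017","PAT17"
"C_L018","PAT18"
"C_L019","THX01"
"C_L020","THX02"
"C_L021","THX03"
"C_L022","THX04"
"C_L023","THX05"
"C_L024","THX06"
"C_L025","COG01"
"C_L026","COG02"
"C_L027","COG03"
"C_L028","COG04"
"C_L029","COG05"
"C_L030","RSK01"
"C_L031","COM01"
"C_L032","UNI01"
"C_L033","UNI02"
"C_L034","UNI03"
"C_L035","UNI04"
"C_L036","UNI05"
"C_L037","UNI06"
"C_L038","UNI07"
"C_L039","UNI08"
"C_L040","UNI09"
"C_L041","UNI10"
"C_L042","UNI11"
"C_L043","UNI12"
"C_L044","UNI13"
"C_L045","ENM01"
"C_L046","ENM02"
"C_L047","ENM03"
"C_L048","RTC01"
"C_L049","RTC02"
"C_L050","RTC03"
"C_L051","RTC04"
"C_L052","RTC05"
"C_L053","RTC06"
"C_L054","RTC07"
"C_L055","RTC08"
"C_L056","RTC09"
"C_L057","RTC10"
"C_L058","EDU01"
"C_L059","EDU02"
"C_L060","EDU03"
"C_L061","EDU04"
"C_L062","EDU05"
"C_L063","EDU06"
"C_L064","INF01"
"C_L065","INF02"
"C_X001",""
"C_X002",""
"C_X003",""
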
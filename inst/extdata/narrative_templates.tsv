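type	template
base	routine health check today, no concerns raised by owner
base	annual booster vaccination given, eating and drinking normally
base	nail clip and weight check, body condition score acceptable
base	owner reports mild scratching, skin looks unremarkable on exam
base	dental check performed, some tartar noted, advised brushing
base	post operative wound check, healing well, sutures intact
base	repeat prescription issued, no new problems reported
base	kennel cough vaccine administered, chest auscultation clear
base	weight clinic visit, diet plan discussed with owner
base	microchip scanned and details confirmed, all fine today
ae	owner reports {term} at home since last night
ae	presented today after an episode of {term} this morning
ae	history of {term} noted, monitoring advised
ae	owner very worried, witnessed {term} in the kitchen yesterday
ae	suspect {term}, discussed referral and further workup
ae	second episode of {term} this week, started on treatment
ae	{term} observed in the waiting room, recovered quickly
ae	telephone advice, owner describes {term}, booked for exam
confound	otherwise dog is fit and well in himself
confound	new harness is a good fit according to owner
confound	owner says cat is fit and well, good appetite
test	bloods run in house, {analyte} {value}, discussed with owner
test	lab results back, {analyte} {value}
test	repeat biochemistry, {analyte} measured at {value}
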
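label	component	alternatives
01402	head	total knee replacement|total knee arthroplasty|knee arthroplasty|knee surgery|knee operation
01402	modifier	left|right|bilateral
01402	tail	with debridement|with partial synovectomy|revision of femoral components|with application of incision management system
01402	acronym	tka=total knee arthroplasty
01400	head	knee arthroscopy|arthroscopy of knee|diagnostic knee arthroscopy|knee surgery|knee operation
01400	modifier	left|right
01400	tail	with meniscectomy|with loose body removal|with lavage and drainage
01214	head	total hip replacement|total hip arthroplasty|hip arthroplasty|hip surgery|hip operation
01214	modifier	left|right|bilateral
01214	tail	with acetabular revision|with femoral head exchange|anterior approach
01214	acronym	tha=total hip arthroplasty
01202	head	hip arthroscopy|arthroscopy of hip|diagnostic hip arthroscopy|hip surgery|hip operation
01202	modifier	left|right
01202	tail	with labral repair|with loose body removal|with femoroplasty
00840	head	laparoscopic appendectomy|appendectomy laparoscopic|removal of appendix|laparoscopy of abdomen|abdominal operation
00840	modifier	urgent|elective
00840	tail	with peritoneal lavage|for perforated appendicitis|with drain placement
00840	acronym	appy=appendectomy
00790	head	laparoscopic cholecystectomy|cholecystectomy laparoscopic|removal of gallbladder|laparoscopy of abdomen|abdominal operation
00790	modifier	urgent|elective
00790	tail	with cholangiogram|for cholelithiasis|with drain placement
00790	acronym	chole=cholecystectomy
00142	head	cataract extraction|phacoemulsification with lens implant|cataract surgery|lens extraction
00142	modifier	left|right
00142	tail	with intraocular lens insertion|topical anesthesia
00142	acronym	phaco=phacoemulsification
00320	head	total thyroidectomy|thyroid lobectomy|excision of thyroid|neck exploration with thyroidectomy
00320	modifier	partial|completion
00320	tail	with lymph node dissection|with nerve monitoring
01961	head	cesarean delivery|cesarean section|repeat cesarean delivery|low transverse cesarean
01961	modifier	primary|repeat
01961	tail	with bilateral tubal ligation|under spinal anesthesia
01961	acronym	cs=cesarean section
00170	head	dental restoration|dental rehabilitation|extraction of teeth|intraoral procedure
00170	modifier	full mouth|pediatric
00170	tail	under general anesthesia|with crowns
00562	head	coronary artery bypass graft|cardiac surgery with bypass|aortic valve replacement|mitral valve repair
00562	modifier	urgent|elective
00562	tail	with cardiopulmonary bypass|redo sternotomy
00562	acronym	cabg=coronary artery bypass graft
01820	head	open reduction internal fixation of wrist fracture|wrist fracture fixation|closed reduction of wrist fracture|distal radius fracture repair
01820	modifier	left|right
01820	tail	with percutaneous pinning|with cast application
01820	acronym	orif=open reduction internal fixation
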
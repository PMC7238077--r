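# Surrogate lexicons for the synthetic corpus generator. All entries are
# invented or generic; none originate from any clinical data set.

.lex_first <- c(
  "James", "Mary", "Robert", "Patricia", "John", "Jennifer", "Michael",
  "Linda", "David", "Elizabeth", "William", "Barbara", "Richard", "Susan",
  "Joseph", "Jessica", "Thomas", "Sarah", "Charles", "Karen", "Daniel",
  "Nancy", "Matthew", "Lisa", "Anthony", "Betty", "Mark", "Margaret",
  "Donald", "Sandra", "Steven", "Ashley", "Paul", "Kimberly", "Andrew",
  "Emily", "Joshua", "Donna", "Kenneth", "Michelle", "Kevin", "Carol",
  "Brian", "Amanda", "George", "Dorothy", "Edward", "Melissa")

.lex_last <- c(
  "Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia", "Miller",
  "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez", "Gonzalez",
  "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson", "Martin",
  "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez", "Clark",
  "Ramirez", "Lewis", "Robinson", "Walker", "Young", "Allen", "King",
  "Wright", "Scott", "Torres", "Nguyen", "Hill", "Flores", "Green",
  "Adams", "Nelson", "Baker", "Hall", "Rivera", "Campbell", "Mitchell",
  "Carter", "Roberts")

.lex_city <- c(
  "Springfield", "Riverton", "Fairview", "Greenville", "Madison",
  "Georgetown", "Salem", "Bristol", "Clinton", "Franklin", "Arlington",
  "Ashland", "Burlington", "Clayton", "Dayton", "Dover", "Hudson",
  "Kingston", "Lexington", "Milton", "Newport", "Oxford", "Winchester",
  "Centerville", "Lakewood", "Oakdale", "Milford", "Chester", "Auburn",
  "Florence")

.lex_state <- c(
  "Alabama", "Alaska", "Arizona", "Colorado", "Delaware", "Florida",
  "Georgia", "Idaho", "Indiana", "Iowa", "Kansas", "Kentucky", "Maine",
  "Maryland", "Michigan", "Missouri", "Montana", "Nebraska", "Nevada",
  "Ohio", "Oregon", "Texas", "Utah", "Vermont", "Virginia", "Wyoming",
  "MA", "NY", "CA", "TX", "OH", "PA")

.lex_country <- c(
  "Canada", "Mexico", "Brazil", "France", "Germany", "Spain", "Italy",
  "Poland", "Sweden", "Norway", "Ireland", "Portugal", "Greece", "Japan",
  "China", "India", "Egypt", "Kenya", "Chile", "Peru", "Australia")

.lex_profession <- c(
  "teacher", "carpenter", "electrician", "farmer", "accountant", "lawyer",
  "engineer", "plumber", "librarian", "musician", "painter", "welder",
  "firefighter", "pharmacist", "waitress", "mechanic", "janitor", "cashier",
  "barber", "tailor", "florist", "driver", "baker", "clerk", "salesman")

.lex_org_stem <- c(
  "Acme", "Globex", "Initech", "Umbrella", "Vandelay", "Sterling",
  "Pinnacle", "Summit", "Beacon", "Harbor", "Keystone", "Liberty",
  "Monarch", "Northstar", "Orion", "Paragon")

.lex_org_suffix <- c("Health", "Insurance", "Industries", "Labs", "Group",
                     "Partners", "Systems")

.lex_hospital_mid <- c("General", "Memorial", "University", "Community",
                       "Regional", "County", "Mercy", "Sacred Heart")

.lex_hospital_suffix <- c("Hospital", "Clinic", "Medical Center",
                          "Health Center", "Infirmary")

.lex_street_suffix <- c("St", "Ave", "Rd", "Blvd", "Ln", "Dr", "Ct", "Way")

.lex_months <- c("January", "February", "March", "April", "May", "June",
                 "July", "August", "September", "October", "November",
                 "December")

.lex_months_abbr <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul",
                      "Aug", "Sep", "Oct", "Nov", "Dec")

.lex_domains <- c("mailhub", "careline", "postbox", "medmail", "inboxly")

# Core clinical/function vocabulary for the filler prose channel; the
# generator extends it with seeded pseudo-words up to the requested
# vocabulary size.
.lex_filler <- c(
  "the", "a", "an", "and", "or", "but", "with", "without", "of", "for",
  "to", "from", "in", "into", "by", "after", "before", "during", "since",
  "was", "is", "are", "were", "been", "has", "had", "have", "will", "would",
  "no", "not", "stable", "acute", "chronic", "mild", "moderate", "severe",
  "patient", "denies", "reports", "presents", "complains", "admitted",
  "discharged", "transferred", "seen", "evaluated", "examined", "followed",
  "treated", "prescribed", "continued", "started", "stopped", "increased",
  "decreased", "tolerated", "improved", "worsened", "resolved", "recurrent",
  "history", "diagnosis", "assessment", "plan", "medication", "dose",
  "daily", "twice", "weekly", "monthly", "review", "followup", "visit",
  "exam", "labs", "imaging", "normal", "abnormal", "elevated", "low",
  "high", "negative", "positive", "unremarkable", "significant",
  "hypertension", "diabetes", "mellitus", "insulin", "glucose", "pressure",
  "blood", "heart", "rate", "rhythm", "murmur", "lungs", "clear", "chest",
  "pain", "shortness", "breath", "edema", "pulse", "temperature", "afebrile",
  "weight", "diet", "exercise", "smoking", "alcohol", "allergies", "none",
  "known", "renal", "hepatic", "cardiac", "pulmonary", "neuro", "intact",
  "alert", "oriented", "mood", "affect", "skin", "warm", "dry", "wound",
  "healing", "well", "sutures", "removed", "incision", "clean", "gait",
  "steady", "fall", "risk", "home", "family", "spouse", "lives", "alone",
  "denied", "fever", "chills", "nausea", "vomiting", "diarrhea", "appetite",
  "good", "sleep", "fatigue", "dizziness", "headache", "vision", "hearing",
  "metformin", "lisinopril", "atorvastatin", "aspirin", "furosemide",
  "omeprazole", "levothyroxine", "amlodipine", "warfarin", "gabapentin",
  "creatinine", "potassium", "sodium", "hemoglobin", "platelets", "wbc",
  "cholesterol", "ldl", "hdl", "a1c", "tsh", "ekg", "echo", "xray", "ct",
  "mri", "ultrasound", "biopsy", "culture", "urine", "specimen", "results",
  "pending", "reviewed", "discussed", "agrees", "refuses", "consent",
  "signed", "return", "clinic", "weeks", "months", "days", "today",
  "yesterday", "morning", "evening", "night", "noted", "observed")
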
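pattern	polarity	category	description
\b[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\.[A-Za-z]{2,}\b	PHI	Email	email address
\bhttps?://[^\s]+	PHI	URL_IP	http or https URL
\bwww\.[A-Za-z0-9.-]+\.[A-Za-z]{2,}\b	PHI	URL_IP	bare www hostname
\b[0-9]{1,3}\.[0-9]{1,3}\.[0-9]{1,3}\.[0-9]{1,3}\b	PHI	URL_IP	dotted-quad IP address
\b[0-9]{3}-[0-9]{2}-[0-9]{4}\b	PHI	Patient_Social_Security_Number	social security number
\(?\b[0-9]{3}\)?[ .-][0-9]{3}[.-][0-9]{4}\b	PHI	Patient_Phone_Fax	US phone or fax number
(?i)\b(?:dob|date of birth)[ :]*[0-9]{1,4}[/.-][0-9]{1,2}[/.-][0-9]{1,4}\b	PHI	Date	date of birth with label
\b[0-9]{4}-[0-9]{2}-[0-9]{2}\b	PHI	Date	ISO date
\b[0-9]{1,2}[/-][0-9]{1,2}[/-][0-9]{2,4}\b	PHI	Date	numeric date
(?i)\b(?:jan(?:uary)?|feb(?:ruary)?|mar(?:ch)?|apr(?:il)?|may|jun(?:e)?|jul(?:y)?|aug(?:ust)?|sep(?:t(?:ember)?)?|oct(?:ober)?|nov(?:ember)?|dec(?:ember)?)\.?\s[0-9]{1,2}(?:st|nd|rd|th)?,?\s[0-9]{4}\b	PHI	Date	month-name date
(?i)\b[0-9]{1,2}\s(?:jan(?:uary)?|feb(?:ruary)?|mar(?:ch)?|apr(?:il)?|may|jun(?:e)?|jul(?:y)?|aug(?:ust)?|sep(?:t(?:ember)?)?|oct(?:ober)?|nov(?:ember)?|dec(?:ember)?)\.?\s[0-9]{4}\b	PHI	Date	day month-name year date
(?<=Dr\. )[A-Z][a-z]+(?: [A-Z][a-z]+)?	PHI	Provider_Name	name after doctor salutation
(?<=Mr\. )[A-Z][a-z]+(?: [A-Z][a-z]+)?	PHI	Name	name after Mr salutation
(?<=Mrs\. )[A-Z][a-z]+(?: [A-Z][a-z]+)?	PHI	Name	name after Mrs salutation
(?<=Ms\. )[A-Z][a-z]+(?: [A-Z][a-z]+)?	PHI	Name	name after Ms salutation
(?i)\b[0-9]{1,5}\s[a-z]+\s(?:street|st|avenue|ave|road|rd|drive|boulevard|blvd|lane|ln|court|ct|place|pl|way)\b	PHI	Patient_Address	street address
\b[A-Z]{2},?\s[0-9]{5}(?:-[0-9]{4})?\b	PHI	Patient_Address	state abbreviation with postal code
(?i)\b(?:mrn|medical record(?: number)?|account(?: number)?|acct)\s?[#:]?\s?[A-Za-z]?[0-9]{4,}\b	PHI	Patient_Unique_ID	record or account number with label
(?i)(?<=license )[A-Z]?[0-9]{4,}\b	PHI	Provider_Certificate_or_License	license number with label
\b[A-Z]{1,3}[0-9]{5,}\b	PHI	Patient_Unique_ID	alphanumeric identifier
\b[0-9]{7,}\b	PHI	Patient_Unique_ID	long digit run identifier
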
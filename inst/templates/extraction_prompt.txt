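You will be given a list of schema variables for an RDF database and a
natural-language question. Your task is to decide which variables the user
wants to retrieve and which (variable, value) parameters constrain the
search. Work through the four steps below, writing brief reasoning under
each heading.

Variables and auxiliary information (one per line: name | example | explanation):
{variables_info}

Question:
{user_question}

Step 1: Extracting User Requests
Identify the keywords in the question that reflect what the user wants to
retrieve.

Step 2: Converting User Request to Variables
Map each extracted keyword to a variable name from the list above. Use only
names that appear in the list.

Step 3: Extracting User-Specified Condition
Identify the filter conditions stated in the question. Copy each condition
value verbatim from the question text, without rephrasing or normalising it.

Step 4: Converting Conditions to Parameters
Map each condition to its variable name, forming (variable, value) pairs.

After the four steps, finish your answer with exactly one fenced code block
tagged json, containing an object with keys "variables" (a list of variable
names) and "parameters" (a list of [variable, value] pairs), for example:

```json
{"variables": ["example_variable"], "parameters": [["example_variable", "example value"]]}
```
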